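#' Plot a tangential vector field
#'
#' Arrow map of microsaccade directions or optic flow over azimuth and
#' elevation, optionally coloured by eye.
#'
#' @param map A `vector_field` tibble.
#' @param arrow_deg Arrow length in degrees of visual angle.
#' @return A ggplot.
#' @export
plot_vector_field <- function(map, arrow_deg = 3) {
  has_eye <- "eye" %in% names(map) && !all(is.na(map$eye))
  p <- ggplot2::ggplot(
    map,
    ggplot2::aes(x = .data$azimuth_deg, y = .data$elevation_deg,
                 xend = .data$azimuth_deg + arrow_deg * .data$vx,
                 yend = .data$elevation_deg + arrow_deg * .data$vy)
  ) +
    ggplot2::geom_segment(
      if (has_eye) ggplot2::aes(colour = .data$eye) else NULL,
      arrow = ggplot2::arrow(length = ggplot2::unit(1.2, "mm")),
      linewidth = 0.3
    ) +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "azimuth (deg)", y = "elevation (deg)")
  if (has_eye) {
    p <- p + ggplot2::scale_colour_manual(values = c(left = "#c0392b",
                                                     right = "#2c6fbb"))
  }
  p + ggplot2::theme_minimal()
}

#' @export
autoplot.vector_field <- function(object, ...) plot_vector_field(object, ...)

#' Plot a direction-map/flow angular-error map
#'
#' @param x A [flow_match_error()] result.
#' @return A ggplot.
#' @export
plot_flow_error <- function(x) {
  ggplot2::ggplot(x$errors,
                  ggplot2::aes(.data$azimuth_deg, .data$elevation_deg,
                               fill = .data$error_deg)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(limits = c(0, 180),
                                  name = "error (deg)") +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "azimuth (deg)", y = "elevation (deg)") +
    ggplot2::theme_minimal()
}

#' Plot projected RF footprints on a virtual plane
#'
#' Draws each RF footprint disk outline at the projection depth.
#'
#' @param projection An [rf_tiling()] result.
#' @param window_mm Optional `c(min, max)` crop applied to both axes.
#' @param max_disks Subsample cap for dense projections.
#' @return A ggplot.
#' @export
plot_rf_tiling <- function(projection, window_mm = NULL, max_disks = 600) {
  pp <- tibble::as_tibble(projection)
  if (!is.null(window_mm)) {
    pp <- dplyr::filter(pp, .data$x_mm >= window_mm[1],
                        .data$x_mm <= window_mm[2],
                        .data$z_mm >= window_mm[1],
                        .data$z_mm <= window_mm[2])
  }
  if (nrow(pp) > max_disks) pp <- dplyr::slice_sample(pp, n = max_disks)
  th <- seq(0, 2 * pi, length.out = 33)
  circles <- purrr::map_dfr(seq_len(nrow(pp)), function(i) {
    tibble::tibble(id = i, eye = pp$eye[i],
                   x = pp$x_mm[i] + pp$radius_mm[i] * cos(th),
                   y = pp$z_mm[i] + pp$radius_mm[i] * sin(th))
  })
  ggplot2::ggplot(circles, ggplot2::aes(.data$x, .data$y, group = .data$id,
                                        colour = .data$eye)) +
    ggplot2::geom_path(alpha = 0.4, linewidth = 0.25) +
    ggplot2::scale_colour_manual(values = c(left = "#c0392b",
                                            right = "#2c6fbb")) +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "x (mm)", y = "z (mm)",
                  title = sprintf("RF footprints at %g mm",
                                  attr(projection, "depth_mm"))) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.rf_projection <- function(object, ...) plot_rf_tiling(object, ...)

#' Plot a depth-error curve
#'
#' Mean relative depth-estimation error against true object distance, with
#' a +/- 1 sd ribbon.
#'
#' @param x A [depth_error_curve()] result.
#' @return A ggplot.
#' @export
plot_depth_error <- function(x) {
  s <- x$summary
  ggplot2::ggplot(s, ggplot2::aes(.data$z_true_mm,
                                  100 * .data$mean_rel_error)) +
    ggplot2::geom_ribbon(
      ggplot2::aes(ymin = 100 * pmax(0, .data$mean_rel_error - .data$sd_rel_error),
                   ymax = 100 * (.data$mean_rel_error + .data$sd_rel_error)),
      alpha = 0.2
    ) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "object distance (mm)",
                  y = "relative depth error (%)") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.depth_error_curve <- function(object, ...) plot_depth_error(object)

#' Plot a response or light time series
#'
#' @param x A `voltage_response` or `light_input`.
#' @return A ggplot.
#' @export
plot_response <- function(x) {
  if (inherits(x, "light_input")) {
    long <- as_tibble.light_input(x)
    ggplot2::ggplot(long, ggplot2::aes(.data$t_ms, .data$intensity,
                                       colour = .data$eye,
                                       group = .data$pr_id)) +
      ggplot2::geom_line(linewidth = 0.3) +
      ggplot2::labs(x = "time (ms)", y = "intensity") +
      ggplot2::theme_minimal()
  } else {
    ggplot2::ggplot(tibble::as_tibble(x),
                    ggplot2::aes(.data$t_ms, .data$v)) +
      ggplot2::geom_line() +
      ggplot2::labs(x = "time (ms)",
                    y = sprintf("response (%s)", attr(x, "stage"))) +
      ggplot2::theme_minimal()
  }
}

#' Plot a resolvability sweep
#'
#' @param sweep A [resolvability_sweep()] tibble.
#' @return A ggplot.
#' @export
plot_resolvability <- function(sweep) {
  ggplot2::ggplot(sweep, ggplot2::aes(.data$wavelength_deg,
                                      .data$modulation_snr,
                                      colour = .data$mode)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(ggplot2::aes(shape = .data$resolvable), size = 2) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "grating wavelength (deg)", y = "modulation SNR") +
    ggplot2::theme_minimal()
}
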