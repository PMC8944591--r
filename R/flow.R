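#' Self-motion optic-flow field on the viewing sphere
#'
#' Computes the apparent-motion vector field induced by rigid self-motion.
#' At viewing direction r the translational component is the tangential
#' projection of -t (magnitude proportional to the sine of the angle between
#' r and t, zero at the poles of the flow field) and the rotational component
#' is `omega x r`; the two add.  Vectors are returned in the local tangent
#' basis (`vx` along increasing azimuth, `vy` along increasing elevation) as
#' unit vectors with the raw magnitude kept separately.
#'
#' @param translation Length-3 numeric, body translation (x right, y forward,
#'   z up); arbitrary units.
#' @param rotation Length-3 numeric, angular velocity vector (same frame).
#' @param grid A data frame with columns `azimuth_deg`, `elevation_deg`, or
#'   NULL for a default 10-degree graticule.
#' @return A `vector_field` tibble: grid columns plus `vx`, `vy`,
#'   `magnitude`.  If both motion components are zero the field is zero and
#'   flagged with attribute `zero_motion`.
#' @export
optic_flow_field <- function(translation = c(0, 1, 0), rotation = c(0, 0, 0),
                             grid = NULL) {
  grid <- grid %||% flow_grid()
  if (!nrow(grid)) stop_domain("`grid` must contain at least one direction.")
  r <- sph_to_cart(grid$azimuth_deg, grid$elevation_deg)
  t_dot_r <- as.numeric(r %*% translation)
  v_t <- r * t_dot_r - matrix(translation, nrow(r), 3, byrow = TRUE)
  v_r <- cbind(
    rotation[2] * r[, 3] - rotation[3] * r[, 2],
    rotation[3] * r[, 1] - rotation[1] * r[, 3],
    rotation[1] * r[, 2] - rotation[2] * r[, 1]
  )
  v <- v_t + v_r
  tb <- tangent_basis(grid$azimuth_deg, grid$elevation_deg)
  vx <- rowSums(v * tb$e_az)
  vy <- rowSums(v * tb$e_el)
  mag <- sqrt(vx^2 + vy^2)
  zero <- all(translation == 0) && all(rotation == 0)
  out <- tibble::tibble(
    azimuth_deg = grid$azimuth_deg, elevation_deg = grid$elevation_deg,
    vx = ifelse(mag > 1e-12, vx / pmax(mag, 1e-300), 0),
    vy = ifelse(mag > 1e-12, vy / pmax(mag, 1e-300), 0),
    magnitude = mag
  )
  structure(out, zero_motion = zero, class = c("vector_field", class(out)))
}

flow_grid <- function(az = seq(-170, 170, by = 10), el = seq(-80, 80, by = 10)) {
  tidyr::crossing(azimuth_deg = az, elevation_deg = el)
}

#' Microsaccade direction map of an eye pair
#'
#' Returns the per-ommatidium microsaccade RF-motion directions as a vector
#' field over both eyes.  The model default sets the fast-phase direction to
#' the local forward-translation optic-flow direction (the slow return phase
#' is its opposite); left- and right-eye maps are mirror images.  A map can
#' instead be loaded from a CSV file with columns `azimuth_deg`,
#' `elevation_deg`, `vx`, `vy`, `eye`; non-unit vectors are normalised on
#' load with a message, and malformed rows raise an error naming the row.
#'
#' @param eye_pair An [build_eye_pair()] result (ignored for file source).
#' @param source `"model"` or `"file"`.
#' @param phase `"fast"` or `"slow"`.
#' @param file CSV path when `source = "file"`.
#' @return A `vector_field` tibble with an `eye` column.
#' @export
microsaccade_direction_map <- function(eye_pair = NULL,
                                       source = c("model", "file"),
                                       phase = c("fast", "slow"),
                                       file = NULL) {
  source <- rlang::arg_match(source)
  phase <- rlang::arg_match(phase)
  sgn <- if (phase == "fast") 1 else -1
  if (source == "model") {
    if (is.null(eye_pair)) stop_domain("`eye_pair` is required for the model map.")
    out <- dplyr::transmute(
      eye_pair$ommatidia,
      eye = .data$eye,
      azimuth_deg = .data$azimuth_deg, elevation_deg = .data$elevation_deg,
      vx = sgn * .data$fast_az, vy = sgn * .data$fast_el,
      magnitude = 1
    )
  } else {
    out <- read_vector_map(file)
    out$vx <- sgn * out$vx
    out$vy <- sgn * out$vy
  }
  structure(out, class = c("vector_field", class(tibble::as_tibble(out))))
}

#' Read a tangent-plane vector map from CSV
#'
#' @param file Path to a CSV with columns `azimuth_deg`, `elevation_deg`,
#'   `vx`, `vy` and optionally `eye`.
#' @return A `vector_field` tibble with unit vectors.
#' @export
read_vector_map <- function(file) {
  tb <- readr::read_csv(file, show_col_types = FALSE)
  need <- c("azimuth_deg", "elevation_deg", "vx", "vy")
  if (!all(need %in% names(tb))) {
    stop_domain(sprintf("Vector map `%s` must have columns %s.",
                        file, paste(need, collapse = ", ")))
  }
  bad <- which(!stats::complete.cases(tb[, need]) |
                 !vapply(seq_len(nrow(tb)),
                         function(i) all(is.finite(unlist(tb[i, need]))),
                         logical(1)))
  if (length(bad)) {
    rlang::abort(sprintf("Vector map `%s`: malformed row %d.", file, bad[1]),
                 class = "saccadeye_parse_error")
  }
  mag <- sqrt(tb$vx^2 + tb$vy^2)
  if (any(mag <= 0)) {
    rlang::abort(sprintf("Vector map `%s`: zero-length vector in row %d.",
                         file, which(mag <= 0)[1]),
                 class = "saccadeye_parse_error")
  }
  if (any(abs(mag - 1) > 1e-6)) {
    rlang::inform(sprintf("Normalised %d non-unit vector(s) on load.",
                          sum(abs(mag - 1) > 1e-6)))
  }
  tb$vx <- tb$vx / mag
  tb$vy <- tb$vy / mag
  tb$magnitude <- 1
  if (!"eye" %in% names(tb)) tb$eye <- NA_character_
  structure(tibble::as_tibble(tb), class = c("vector_field", "tbl_df", "tbl", "data.frame"))
}

#' Write a vector map to CSV
#' @param map A `vector_field` tibble.
#' @param file Output path.
#' @export
write_vector_map <- function(map, file) {
  cols <- intersect(c("eye", "azimuth_deg", "elevation_deg", "vx", "vy",
                      "magnitude"), names(map))
  readr::write_csv(dplyr::select(map, dplyr::all_of(cols)), file)
  invisible(file)
}

#' Angular error between two vector fields
#'
#' Compares two unit vector fields defined on the same grid and returns the
#' per-point angle between them (0 to 180 degrees) together with summary
#' statistics.  Used to compare microsaccade direction maps with self-motion
#' optic-flow fields.
#'
#' @param map_a,map_b `vector_field` tibbles on identical grids (matched on
#'   azimuth, elevation and, when present in both, eye).
#' @return An object of class `flow_match`: a list with `errors` (per-point
#'   tibble including `error_deg`) and `stats` (median, mean, n).
#' @export
flow_match_error <- function(map_a, map_b) {
  keys <- c("azimuth_deg", "elevation_deg")
  if ("eye" %in% names(map_a) && "eye" %in% names(map_b)) keys <- c("eye", keys)
  a <- dplyr::arrange(tibble::as_tibble(map_a),
                      dplyr::across(dplyr::all_of(keys)))
  b <- dplyr::arrange(tibble::as_tibble(map_b),
                      dplyr::across(dplyr::all_of(keys)))
  if (nrow(a) != nrow(b) ||
      !isTRUE(all.equal(as.data.frame(a[keys]), as.data.frame(b[keys]),
                        tolerance = 1e-9, check.attributes = FALSE))) {
    stop_domain("Vector fields are defined on different grids.")
  }
  dot <- a$vx * b$vx + a$vy * b$vy
  err <- rad2deg(acos(pmin(1, pmax(-1, dot))))
  errors <- dplyr::bind_cols(a[keys], tibble::tibble(error_deg = err))
  structure(
    list(
      errors = errors,
      stats = tibble::tibble(
        median_deg = stats::median(err),
        mean_deg = mean(err),
        n = length(err)
      )
    ),
    class = "flow_match"
  )
}

#' @export
print.flow_match <- function(x, ...) {
  cat("<flow_match>\n")
  cat(sprintf("  %d grid points; median error %.2f deg, mean %.2f deg\n",
              x$stats$n, x$stats$median_deg, x$stats$mean_deg))
  invisible(x)
}

# Forward-flow field evaluated on the same grid as a direction map.
flow_on_map_grid <- function(map, translation = c(0, 1, 0),
                             rotation = c(0, 0, 0)) {
  fl <- optic_flow_field(translation, rotation,
                         grid = map[, c("azimuth_deg", "elevation_deg")])
  if ("eye" %in% names(map)) fl <- dplyr::mutate(fl, eye = map$eye, .before = 1)
  fl
}
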