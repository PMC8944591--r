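#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a depth-error curve
#'
#' @param x A [depth_error_curve()] result.
#' @param ... Unused.
#' @return The per-depth summary tibble (mean/sd relative error, failure
#'   rate).
#' @export
tidy.depth_error_curve <- function(x, ...) x$summary

#' One-row overview of a depth-error curve
#'
#' @param x A [depth_error_curve()] result.
#' @param ... Unused.
#' @return A one-row tibble: depth range, worst mean error, overall failure
#'   rate, monotonicity direction of the decoder calibration.
#' @export
glance.depth_error_curve <- function(x, ...) {
  tibble::tibble(
    n_depths = nrow(x$summary),
    z_min_mm = min(x$summary$z_true_mm),
    z_max_mm = max(x$summary$z_true_mm),
    max_mean_rel_error = max(x$summary$mean_rel_error, na.rm = TRUE),
    failure_rate = mean(x$trials$failed),
    n_trials = x$n_trials,
    direction = x$calibration$direction
  )
}

#' Tidy an ablation result
#' @param x An [ablation_experiment()] result.
#' @param ... Unused.
#' @return The per-arm summary tibble.
#' @export
tidy.ablation_result <- function(x, ...) x$summary

#' One-row overview of an ablation result
#' @param x An [ablation_experiment()] result.
#' @param ... Unused.
#' @return A one-row tibble with the error penalty of the ablated arm.
#' @export
glance.ablation_result <- function(x, ...) {
  ctl <- x$summary[x$summary$arm == "control", ]
  abl <- x$summary[x$summary$arm != "control", ]
  tibble::tibble(
    mode = x$mode, z_mm = x$z_mm,
    control_error = ctl$mean_rel_error,
    ablated_error = abl$mean_rel_error,
    ablated_failure_rate = abl$failure_rate,
    n = ctl$n
  )
}

#' Tidy a direction-map/flow comparison
#' @param x A [flow_match_error()] result.
#' @param ... Unused.
#' @return The per-grid-point error tibble.
#' @export
tidy.flow_match <- function(x, ...) x$errors

#' One-row overview of a direction-map/flow comparison
#' @param x A [flow_match_error()] result.
#' @param ... Unused.
#' @return The summary statistics tibble.
#' @export
glance.flow_match <- function(x, ...) x$stats

#' Tidy a depth calibration
#' @param x A [calibrate_depth_model()] result.
#' @param ... Unused.
#' @return The `delta_t(z)` lookup tibble.
#' @export
tidy.depth_calibration <- function(x, ...) x$table

#' One-row overview of a depth calibration
#' @param x A [calibrate_depth_model()] result.
#' @param ... Unused.
#' @return A one-row tibble: reference speed, monotonicity, direction.
#' @export
glance.depth_calibration <- function(x, ...) {
  tibble::tibble(
    omega_ref_dps = x$omega_ref_dps,
    n_depths = nrow(x$table),
    monotone = x$monotone,
    direction = x$direction
  )
}
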