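#' Inter-eye response time disparity
#'
#' Signed lag (ms) maximising the normalised cross-correlation between the
#' left and right response waveforms, refined by parabolic interpolation
#' around the discrete peak for sub-sample precision.  Positive means the
#' left response leads.
#'
#' @param left,right `voltage_response` objects (or numeric vectors with
#'   `dt_ms`) on a common time base; both must be non-flat.
#' @param dt_ms Sampling interval when bare vectors are given.
#' @param max_lag_ms Search half-window (ms).
#' @return Signed lag in ms.
#' @export
time_disparity <- function(left, right, dt_ms = NULL, max_lag_ms = 400) {
  x <- if (is.data.frame(left)) left$v else as.numeric(left)
  y <- if (is.data.frame(right)) right$v else as.numeric(right)
  if (is.null(dt_ms)) {
    dt_ms <- if (is.data.frame(left) && nrow(left) > 1) {
      left$t_ms[2] - left$t_ms[1]
    } else {
      1
    }
  }
  if (length(x) != length(y)) stop_domain("Responses must share a time base.")
  x <- x - mean(x)
  y <- y - mean(y)
  if (stats::sd(x) < 1e-12 || stats::sd(y) < 1e-12) {
    rlang::abort("Time disparity is undefined for flat response(s).",
                 class = "saccadeye_flat_error")
  }
  n <- length(x)
  lmax <- min(n - 8L, as.integer(round(max_lag_ms / dt_ms)))
  lags <- -lmax:lmax
  # per-lag Pearson correlation of the overlapping segments: unbiased with
  # respect to lag (a plain windowed cross-product drags the peak toward
  # zero lag on waveforms with long plateaus)
  cc <- vapply(lags, function(l) {
    xi <- if (l >= 0) x[seq_len(n - l)] else x[seq_len(n + l) - l]
    yi <- if (l >= 0) y[seq_len(n - l) + l] else y[seq_len(n + l)]
    if (stats::sd(xi) < 1e-14 || stats::sd(yi) < 1e-14) return(-Inf)
    stats::cor(xi, yi)
  }, numeric(1))
  i <- which.max(cc)
  if (i == 1 || i == length(lags)) {
    return(lags[i] * dt_ms)
  }
  num <- cc[i - 1] - cc[i + 1]
  den <- cc[i - 1] - 2 * cc[i] + cc[i + 1]
  frac <- if (abs(den) > 1e-15) 0.5 * num / den else 0
  (lags[i] + frac) * dt_ms
}

#' Velocity estimate from neighbouring photoreceptors
#'
#' Correlates the response of a photoreceptor with that of its neighbour
#' along the motion direction: the angular velocity is the known angular
#' separation divided by the measured lag.  Used to velocity-normalise
#' time-disparity depth estimates.
#'
#' @param first,second Responses of the photoreceptor crossed first and of
#'   its along-motion neighbour (same eye).
#' @param delta_phi_deg Angular separation of the two RF centres (degrees).
#' @param dt_ms Sampling interval for bare vectors.
#' @return Signed angular velocity estimate (deg/s).
#' @export
velocity_estimate <- function(first, second, delta_phi_deg = 4.5,
                              dt_ms = NULL) {
  assert_scalar_pos(delta_phi_deg, "delta_phi_deg")
  lag <- time_disparity(first, second, dt_ms = dt_ms)
  dt <- dt_ms %||%
    (if (is.data.frame(first) && nrow(first) > 1) first$t_ms[2] - first$t_ms[1] else 1)
  if (abs(lag) < 2 * dt) {
    rlang::abort("Neighbour lag is too small; velocity is undefined.",
                 class = "saccadeye_velocity_error")
  }
  delta_phi_deg / (lag / 1000)
}

#' Depth from time disparity
#'
#' Decodes object depth from the inter-eye time disparity and the estimated
#' angular velocity.  The closed-form baseline inverts the static
#' triangulation of coincident-axis photoreceptor pairs,
#' `z = k / (2 tan(omega * delta_t / 2))`; the calibrated mode (default
#' whenever a calibration is supplied) inverts a monotone `delta_t(z)`
#' lookup built by forward simulation of the full dynamic model, after
#' velocity-normalising the measured disparity to the calibration speed.
#'
#' @param delta_t_ms Measured inter-eye disparity (ms).
#' @param omega_dps Estimated angular velocity (deg/s).
#' @param baseline_mm Inter-eye baseline for the closed form (mm).
#' @param calibration A [calibrate_depth_model()] result, or NULL for the
#'   closed form.
#' @return Decoded depth (mm); calibrated estimates outside the calibration
#'   range are clamped to its ends and flagged with attribute
#'   `out_of_range`.
#' @export
estimate_depth <- function(delta_t_ms, omega_dps, baseline_mm = 0.4,
                           calibration = NULL) {
  if (is.null(calibration)) {
    if (delta_t_ms <= 0) {
      rlang::abort("Closed-form depth needs a positive time disparity.",
                   class = "saccadeye_range_error")
    }
    ang <- deg2rad(omega_dps) * delta_t_ms / 1000
    return(baseline_mm / (2 * tan(ang / 2)))
  }
  dt_adj <- delta_t_ms * omega_dps / calibration$omega_ref_dps
  knots <- calibration$table
  xs <- knots$delta_t_ms
  zs <- knots$z_mm
  n <- length(xs)
  oor <- dt_adj < xs[1] || dt_adj > xs[n]
  z <- if (!oor) {
    stats::approx(xs, zs, xout = dt_adj, ties = "ordered")$y
  } else if (dt_adj < xs[1]) {
    # linear extrapolation from the end segments: disparities beyond the
    # calibrated range decode to increasingly uncertain depths rather than
    # saturating at the table edge
    zs[1] + (zs[2] - zs[1]) / (xs[2] - xs[1]) * (dt_adj - xs[1])
  } else {
    zs[n] + (zs[n] - zs[n - 1]) / (xs[n] - xs[n - 1]) * (dt_adj - xs[n])
  }
  z <- min(max(z, 0.25 * min(zs)), 3 * max(zs))
  structure(z, out_of_range = oor)
}

# ---- end-to-end depth pipeline ------------------------------------------

#' Depth-experiment scenario
#'
#' Stimulus and readout configuration for the moving-dot depth experiments:
#' two dark dots 3.5 degrees apart travelling left to right at 50 deg/s,
#' read out by the corresponding left/right R6 pair of the frontal
#' ommatidium plus the left-eye along-motion neighbour R6 used for velocity
#' normalisation.
#'
#' @param separation_deg,speed_dps,dot_deg,start_az_deg Dot-pair scene
#'   parameters (see [make_dot_pair()]).
#' @param cell Readout photoreceptor class.
#' @param mode Sampling mode passed to [render_binocular()].
#' @return A list of class `depth_scenario`.
#' @export
depth_scenario <- function(separation_deg = 3.5, speed_dps = 50,
                           dot_deg = 1.7, start_az_deg = -15,
                           cell = "R6", mode = "microsaccadic",
                           settle_ms = 150) {
  structure(list(separation_deg = separation_deg, speed_dps = speed_dps,
                 dot_deg = dot_deg, start_az_deg = start_az_deg,
                 cell = cell, mode = mode, settle_ms = settle_ms),
            class = "depth_scenario")
}

# Drop the filter/kinematics settling transient and the trailing margin
# (post-transit recovery drift is common to both eyes and biases the
# correlation peak toward zero lag) before waveform analysis.
crop_v <- function(v, settle_ms, tail_ms = settle_ms) {
  v$v[v$t_ms >= settle_ms & v$t_ms <= max(v$t_ms) - tail_ms]
}

# Readout photoreceptors: the corresponding left/right pair of the frontal
# ommatidium and the left-eye neighbours one and two interommatidial steps
# along the motion direction (two neighbour lags stabilise the velocity
# estimate).
depth_readout <- function(eye_pair, scenario) {
  pair0 <- corresponding_pair(eye_pair, scenario$cell, 0, 0)
  dphi <- eye_pair$config$interommatidial_deg
  left_all <- dplyr::filter(eye_pair$ommatidia, .data$eye == "left")
  nb_pr <- function(az) {
    d <- ang_dist_deg(az, 0, left_all$azimuth_deg, left_all$elevation_deg)
    nb_omm <- left_all$omm_id[which.min(d)]
    dplyr::filter(eye_pair$photoreceptors, .data$eye == "left",
                  .data$omm_id == nb_omm, .data$cell == scenario$cell)
  }
  nbr <- nb_pr(dphi)
  nbr2 <- nb_pr(2 * dphi)
  list(
    left = dplyr::filter(pair0, .data$eye == "left"),
    right = dplyr::filter(pair0, .data$eye == "right"),
    neighbor = nbr,
    neighbor2 = nbr2,
    prs = dplyr::bind_rows(pair0, nbr, nbr2)
  )
}

# Combined velocity estimate from the lags of two along-motion neighbours
# (delta_phi and 2 delta_phi away): omega = 3 delta_phi / (lag1 + lag2).
velocity_from_neighbors <- function(x, n1, n2, delta_phi_deg, dt_ms) {
  lag1 <- time_disparity(x, n1, dt_ms = dt_ms)
  lag2 <- time_disparity(x, n2, dt_ms = dt_ms)
  denom <- lag1 + lag2
  if (abs(denom) < 4 * dt_ms || sign(lag1) != sign(lag2)) {
    rlang::abort("Neighbour lags are too small; velocity is undefined.",
                 class = "saccadeye_velocity_error")
  }
  3 * delta_phi_deg / (denom / 1000)
}

# Deterministic closed-loop rendering of the depth scene for the readout
# photoreceptors; returns the light matrix plus readout ids.
depth_render <- function(eye_pair, z_mm, scenario, kinematics,
                         mode = scenario$mode, ...) {
  scene <- make_dot_pair(
    separation_deg = scenario$separation_deg, speed_dps = scenario$speed_dps,
    depth_mm = z_mm, dot_deg = scenario$dot_deg,
    start_az_deg = scenario$start_az_deg,
    # margin past the nominal transit so the farthest neighbour's response
    # is not clipped
    duration_ms = 1000 * (2 * abs(scenario$start_az_deg) +
                            scenario$separation_deg) / scenario$speed_dps + 150
  )
  ro <- depth_readout(eye_pair, scenario)
  li <- render_binocular(scene, eye_pair, photoreceptors = ro$prs,
                         kinematics = kinematics, mode = mode, ...)
  list(light = li, readout = ro)
}

# One depth measurement from four response waveforms (settling transient
# removed before cross-correlation).
decode_depth <- function(v_left, v_right, v_nbr, v_nbr2, delta_phi_deg,
                         calibration, baseline_mm, settle_ms = 150,
                         dt_ms = 1) {
  dt_lr <- time_disparity(crop_v(v_left, settle_ms),
                          crop_v(v_right, settle_ms), dt_ms = dt_ms)
  omega <- velocity_from_neighbors(crop_v(v_left, settle_ms),
                                   crop_v(v_nbr, settle_ms),
                                   crop_v(v_nbr2, settle_ms),
                                   delta_phi_deg, dt_ms)
  z <- estimate_depth(dt_lr, omega, baseline_mm, calibration)
  list(delta_t_ms = dt_lr, omega_dps = omega, z_hat_mm = as.numeric(z),
       out_of_range = isTRUE(attr(z, "out_of_range")))
}

#' Calibrate the time-disparity depth decoder
#'
#' Forward-simulates the full deterministic pipeline (closed-loop render at
#' the scenario speed, surrogate phototransduction, cross-correlation
#' disparity and neighbour-correlation velocity) over a grid of depths and
#' tabulates the velocity-normalised `delta_t(z)` relation.  The relation
#' must be strictly monotone for decoding to be well-posed; its empirical
#' direction is recorded.
#'
#' @param eye_pair An [build_eye_pair()] result.
#' @param z_grid_mm Calibration depths (mm).
#' @param scenario A [depth_scenario()].
#' @param kinematics A [kinetics_params()].
#' @param pr_params A [photoreceptor_params()].
#' @return An object of class `depth_calibration`: the lookup `table`
#'   (sorted by `delta_t_ms`), the reference speed, the monotonicity
#'   direction (`"shorter_when_closer"` or `"longer_when_closer"`), and the
#'   scenario.
#' @export
calibrate_depth_model <- function(eye_pair,
                                  z_grid_mm = c(2, 3, 5, 8, 12, 18, 25, 35,
                                                50, 70, 100, 140, 200, 280,
                                                400),
                                  scenario = depth_scenario(),
                                  kinematics = kinetics_params(),
                                  pr_params = photoreceptor_params()) {
  dphi <- eye_pair$config$interommatidial_deg
  rows <- purrr::map_dfr(z_grid_mm, function(z) {
    dr <- depth_render(eye_pair, z, scenario, kinematics)
    vs <- lapply(
      list(dr$readout$left$pr_id, dr$readout$right$pr_id,
           dr$readout$neighbor$pr_id, dr$readout$neighbor2$pr_id),
      function(id) adaptive_response(light_series(dr$light, id), pr_params)
    )
    st <- scenario$settle_ms
    dt_lr <- time_disparity(crop_v(vs[[1]], st), crop_v(vs[[2]], st),
                            dt_ms = dr$light$dt_ms)
    omega <- velocity_from_neighbors(crop_v(vs[[1]], st), crop_v(vs[[3]], st),
                                     crop_v(vs[[4]], st), dphi,
                                     dr$light$dt_ms)
    tibble::tibble(z_mm = z, delta_t_raw_ms = dt_lr, omega_hat_dps = omega)
  })
  omega_ref <- scenario$speed_dps
  rows$delta_t_ms <- rows$delta_t_raw_ms * rows$omega_hat_dps / omega_ref
  dd <- diff(rows$delta_t_ms[order(rows$z_mm)])
  monotone <- all(dd > 0) || all(dd < 0)
  # direction of the magnitude: does a closer object give a shorter or a
  # longer inter-eye time difference?
  dd_abs <- diff(abs(rows$delta_t_ms)[order(rows$z_mm)])
  direction <- if (mean(sign(dd_abs)) >= 0) {
    "shorter_when_closer"
  } else {
    "longer_when_closer"
  }
  if (!monotone) {
    rlang::warn("delta_t(z) is not strictly monotone over the calibration grid.")
  }
  structure(
    list(table = dplyr::arrange(rows, .data$delta_t_ms),
         omega_ref_dps = omega_ref, monotone = monotone,
         direction = direction, scenario = scenario,
         z_grid_mm = z_grid_mm),
    class = "depth_calibration"
  )
}

#' @export
print.depth_calibration <- function(x, ...) {
  cat("<depth_calibration>\n")
  cat(sprintf("  %d depths in [%g, %g] mm at %g deg/s; monotone: %s (%s)\n",
              nrow(x$table), min(x$table$z_mm), max(x$table$z_mm),
              x$omega_ref_dps, x$monotone, x$direction))
  invisible(x)
}

# Run n_trials stochastic depth estimates at one depth under one sampling
# mode.  The deterministic closed-loop light is rendered once; per-trial
# stochasticity is photon (Poisson absorption) noise and bump latency
# jitter in the phototransduction stage.  Trial seeds are derived from
# `seed` so ablation arms can be run on paired seeds.
run_depth_trials <- function(eye_pair, z_mm, n_trials, calibration,
                             scenario = depth_scenario(),
                             kinematics = kinetics_params(),
                             pr_params = photoreceptor_params(),
                             mode = "microsaccadic", seed = 1, ...) {
  dr <- depth_render(eye_pair, z_mm, scenario, kinematics, mode = mode, ...)
  dphi <- eye_pair$config$interommatidial_deg
  k <- eye_pair$config$baseline_mm
  ids <- c(dr$readout$left$pr_id, dr$readout$right$pr_id,
           dr$readout$neighbor$pr_id, dr$readout$neighbor2$pr_id)
  lights <- lapply(ids, function(id) light_series(dr$light, id))
  purrr::map_dfr(seq_len(n_trials), function(tr) {
    set.seed(seed + tr)
    vs <- lapply(lights, function(li) bump_response(li, pr_params))
    res <- tryCatch(
      decode_depth(vs[[1]], vs[[2]], vs[[3]], vs[[4]], dphi, calibration, k,
                   settle_ms = scenario$settle_ms,
                   dt_ms = dr$light$dt_ms),
      saccadeye_flat_error = function(e) NULL,
      saccadeye_velocity_error = function(e) NULL,
      saccadeye_range_error = function(e) NULL
    )
    if (is.null(res)) {
      tibble::tibble(z_true_mm = z_mm, trial = tr, delta_t_ms = NA_real_,
                     omega_dps = NA_real_, z_hat_mm = NA_real_,
                     rel_error = NA_real_, failed = TRUE, seed = seed + tr)
    } else {
      tibble::tibble(z_true_mm = z_mm, trial = tr,
                     delta_t_ms = res$delta_t_ms, omega_dps = res$omega_dps,
                     z_hat_mm = res$z_hat_mm,
                     rel_error = abs(res$z_hat_mm - z_mm) / z_mm,
                     failed = FALSE, seed = seed + tr)
    }
  })
}

#' Depth-estimation error versus object distance
#'
#' Simulates the moving-dot depth experiment end to end (closed-loop
#' render, stochastic phototransduction, cross-correlation time disparity,
#' neighbour-correlation velocity normalisation, calibrated depth decoding)
#' over a set of object distances and aggregates the relative errors.
#'
#' @param eye_pair An [build_eye_pair()] result.
#' @param z_mm Object distances (mm).
#' @param n_trials Stochastic trials per distance (>= 2).
#' @param calibration A [calibrate_depth_model()] result (built with the
#'   same scenario and parameters if omitted).
#' @param scenario,kinematics,pr_params Pipeline parameters.
#' @param seed Base seed; trial seeds are `seed + trial`.
#' @return An object of class `depth_error_curve`: `trials` (per-trial
#'   tibble) and `summary` (per-depth mean/sd relative error and failure
#'   rate).  [tidy()] returns the summary, [glance()] the overall picture.
#' @export
depth_error_curve <- function(eye_pair, z_mm = c(25, 50, 100, 200),
                              n_trials = 100, calibration = NULL,
                              scenario = depth_scenario(),
                              kinematics = kinetics_params(),
                              pr_params = photoreceptor_params(),
                              seed = 1) {
  if (any(z_mm <= 0)) stop_domain("Depths must be positive.")
  if (n_trials < 2) stop_domain("`n_trials` must be at least 2.")
  calibration <- calibration %||%
    calibrate_depth_model(eye_pair, scenario = scenario,
                          kinematics = kinematics, pr_params = pr_params)
  trials <- purrr::map_dfr(seq_along(z_mm), function(i) {
    run_depth_trials(eye_pair, z_mm[i], n_trials, calibration,
                     scenario = scenario, kinematics = kinematics,
                     pr_params = pr_params, seed = seed + 10000L * (i - 1L))
  })
  summary <- dplyr::summarise(
    dplyr::group_by(trials, .data$z_true_mm),
    mean_rel_error = mean(.data$rel_error, na.rm = TRUE),
    sd_rel_error = stats::sd(.data$rel_error, na.rm = TRUE),
    failure_rate = mean(.data$failed),
    n = dplyr::n(),
    .groups = "drop"
  )
  structure(
    list(trials = trials, summary = summary, calibration = calibration,
         seed = seed, n_trials = n_trials),
    class = "depth_error_curve"
  )
}

#' @export
print.depth_error_curve <- function(x, ...) {
  cat("<depth_error_curve>\n")
  print(x$summary)
  invisible(x)
}

#' Sampling-mode ablations of the depth estimator
#'
#' Reruns the depth experiment with a degraded sampling mode on the same
#' trial seeds as the mirror-symmetric binocular control: `"monocular"`
#' (one eye zeroed; the disparity is undefined and every trial fails),
#' `"asynchronous"` (one eye's sampling delayed by `phase_ms`), or
#' `"asymmetric"` (one eye's microsaccades disabled).
#'
#' @param eye_pair An [build_eye_pair()] result.
#' @param mode Ablation mode.
#' @param z_mm Object distance (mm).
#' @param n_trials Paired trials per arm.
#' @param phase_ms Kinematic delay for the asynchronous mode.
#' @param calibration,scenario,kinematics,pr_params,seed As in
#'   [depth_error_curve()].
#' @return An object of class `ablation_result` with per-arm `trials` and
#'   `summary` (mean relative error and failure rate).
#' @export
ablation_experiment <- function(eye_pair,
                                mode = c("asynchronous", "asymmetric",
                                         "monocular"),
                                z_mm = 25, n_trials = 100, phase_ms = 20,
                                calibration = NULL,
                                scenario = depth_scenario(),
                                kinematics = kinetics_params(),
                                pr_params = photoreceptor_params(),
                                seed = 1) {
  mode <- rlang::arg_match(mode)
  calibration <- calibration %||%
    calibrate_depth_model(eye_pair, scenario = scenario,
                          kinematics = kinematics, pr_params = pr_params)
  args <- list(eye_pair = eye_pair, z_mm = z_mm, n_trials = n_trials,
               calibration = calibration, scenario = scenario,
               kinematics = kinematics, pr_params = pr_params, seed = seed)
  control <- do.call(run_depth_trials, c(args, list(mode = "microsaccadic")))
  ablated <- do.call(run_depth_trials, c(
    args,
    list(mode = mode),
    if (mode == "asynchronous") list(phase_ms = phase_ms) else list(),
    if (mode == "monocular") list(side = "left") else list()
  ))
  trials <- dplyr::bind_rows(
    dplyr::mutate(control, arm = "control"),
    dplyr::mutate(ablated, arm = mode)
  )
  summary <- dplyr::summarise(
    dplyr::group_by(trials, .data$arm),
    mean_rel_error = mean(.data$rel_error, na.rm = TRUE),
    failure_rate = mean(.data$failed),
    n = dplyr::n(),
    .groups = "drop"
  )
  structure(list(trials = trials, summary = summary, mode = mode,
                 z_mm = z_mm, phase_ms = phase_ms, seed = seed),
            class = "ablation_result")
}

#' @export
print.ablation_result <- function(x, ...) {
  cat(sprintf("<ablation_result> mode %s at z = %g mm\n", x$mode, x$z_mm))
  print(x$summary)
  invisible(x)
}

#' Export depth-experiment trials as CSV + JSON summary
#'
#' @param x A `depth_error_curve` or `ablation_result`.
#' @param path Base path without extension.
#' @return `path`, invisibly.
#' @export
export_depth_results <- function(x, path) {
  readr::write_csv(x$trials, paste0(path, ".csv"))
  jsonlite::write_json(
    list(summary = x$summary, seed = x$seed),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA,
    dataframe = "columns"
  )
  invisible(path)
}
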