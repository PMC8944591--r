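#' Static "old theory" contrast of a hidden dot
#'
#' Quantifies how visible a fine dot is to a static compound eye: both the
#' dot scene and its dotless control are blurred by a circular Gaussian
#' receptive field, and the peak absolute difference of the blurred scenes
#' is expressed as a percentage of the stripe pattern's own peak-to-trough
#' contrast.  With the defaults (a 0.98 degree black dot on 1.2 degree
#' black/white stripes seen through a 5.4 degree half-width RF) the dot
#' changes the photoreceptor image by only about 1.6% of the stripe
#' contrast, i.e. it is buried in response noise for a static eye.
#'
#' The RF half-width `h` is mapped to the Gaussian as `sigma = h / 2`
#' (the stated width spans the two e^(-1/2) sensitivity points), the
#' convention of this analysis.
#'
#' @param scene_with_dot A `scene` (e.g. [make_hidden_dot_scene()]).
#' @param scene_control The dotless control; defaults to
#'   `scene_with_dot$control`.
#' @param rf_halfwidth_deg RF half-width (degrees).
#' @param grid_deg Raster resolution (degrees).
#' @param window_deg Analysis half-window around the dot (degrees).
#' @param relative Return the percentage of the control's peak-to-trough
#'   contrast (default); with `FALSE` only absolute quantities are
#'   computed, for scenes with a contrast-free control.
#' @return A one-row tibble: `peak_diff` (absolute blurred difference),
#'   `control_contrast` (raw peak-to-trough of the control) and
#'   `relative_pct`.
#' @export
static_contrast_metric <- function(scene_with_dot, scene_control = NULL,
                                   rf_halfwidth_deg = 5.4, grid_deg = 0.05,
                                   window_deg = 8, relative = TRUE) {
  scene_control <- scene_control %||% scene_with_dot$control
  if (is.null(scene_control)) {
    stop_domain("No control scene supplied (and none attached to the scene).")
  }
  same_grating <- identical(is.null(scene_with_dot$grating),
                            is.null(scene_control$grating)) &&
    (is.null(scene_with_dot$grating) ||
       isTRUE(all.equal(scene_with_dot$grating, scene_control$grating)))
  if (!same_grating || scene_with_dot$background != scene_control$background) {
    stop_domain("Dot and control scenes must share geometry and background.")
  }
  assert_scalar_pos(rf_halfwidth_deg, "rf_halfwidth_deg")
  sigma <- rf_halfwidth_deg / 2
  pad <- ceiling(4 * sigma)
  ctr <- if (nrow(scene_with_dot$objects)) {
    c(scene_with_dot$objects$az_deg[1], scene_with_dot$objects$el_deg[1])
  } else {
    c(0, 0)
  }
  az_range <- ctr[1] + c(-1, 1) * (window_deg + pad)
  el_range <- ctr[2] + c(-1, 1) * (window_deg + pad)
  a <- raster_scene(scene_with_dot, az_range, el_range, grid_deg)
  b <- raster_scene(scene_control, az_range, el_range, grid_deg)
  kern <- gauss_kernel_1d(sigma, grid_deg)
  # blurring is linear, so the peak of |blur(a) - blur(b)| equals the peak
  # of |blur(a - b)|; a - b is compactly supported around the dot
  cd <- blur_separable(a - b, kern)
  half <- (length(kern) - 1) / 2
  keep_r <- (half + 1):(nrow(cd) - half)
  keep_c <- (half + 1):(ncol(cd) - half)
  diff_peak <- max(abs(cd[keep_r, keep_c]))
  control_contrast <- max(b) - min(b)
  rel <- if (relative) {
    if (control_contrast <= 0) {
      stop_domain("Control scene has zero contrast; relative metric undefined.")
    }
    100 * diff_peak / control_contrast
  } else {
    NA_real_
  }
  tibble::tibble(peak_diff = diff_peak, control_contrast = control_contrast,
                 relative_pct = rel)
}

gauss_kernel_1d <- function(sigma_deg, grid_deg) {
  half <- ceiling(4 * sigma_deg / grid_deg)
  k <- stats::dnorm(seq(-half, half) * grid_deg, 0, sigma_deg)
  k / sum(k)
}

# Separable Gaussian blur of a matrix via a single 2D FFT; returns the
# "same"-size central part of the convolution (edges are only valid once
# callers crop half a kernel width, as static_contrast_metric does).
blur_separable <- function(m, kern) {
  k <- length(kern)
  half <- (k - 1) / 2
  pr <- stats::nextn(nrow(m) + k - 1, c(2, 3, 5))
  pc <- stats::nextn(ncol(m) + k - 1, c(2, 3, 5))
  pm <- matrix(0, pr, pc)
  pm[seq_len(nrow(m)), seq_len(ncol(m))] <- m
  ky <- c(kern, numeric(pr - k))
  kx <- c(kern, numeric(pc - k))
  full <- Re(stats::fft(stats::fft(pm) * (stats::fft(ky) %o% stats::fft(kx)),
                        inverse = TRUE)) / (pr * pc)
  full[half + seq_len(nrow(m)), half + seq_len(ncol(m))]
}

#' Grating resolvability through the dynamic sampling pipeline
#'
#' Drives a single frontal photoreceptor with a drifting square-wave
#' grating through the full pipeline (closed-loop or static rendering,
#' stochastic bump phototransduction) and measures the modulation
#' signal-to-noise ratio: the coherent response power at the grating's
#' temporal frequency relative to the stochastic (noise-floor) power at
#' that frequency, estimated phase-coherently across record segments.
#' The grating is called resolvable when the SNR reaches the configured
#' threshold.
#' Microsaccadic sampling narrows the RF while it moves, which recovers
#' hyperacute (finer than the interommatidial angle) gratings that a
#' static eye blurs away.
#'
#' @param eye_pair An [build_eye_pair()] result.
#' @param wavelength_deg Grating wavelength (degrees).
#' @param speed_dps Drift speed (deg/s).
#' @param mode `"static"` or `"microsaccadic"`.
#' @param contrast Grating contrast.
#' @param duration_ms Stimulus duration (the first `settle_ms` are
#'   discarded before spectral analysis).
#' @param settle_ms Transient discarded from the analysis window.
#' @param threshold SNR criterion for resolvability.
#' @param kinematics,pr_params Pipeline parameters.
#' @param seed Seed for the stochastic phototransduction.
#' @return A one-row `resolvability` tibble: wavelength, speed, mode,
#'   `modulation_snr`, `resolvable`, stimulus frequency and seed.
#' @export
dynamic_resolvability <- function(eye_pair, wavelength_deg, speed_dps = 50,
                                  mode = c("microsaccadic", "static"),
                                  contrast = 1, duration_ms = 3000,
                                  settle_ms = 500, threshold = 2,
                                  kinematics = kinetics_params(),
                                  pr_params = photoreceptor_params(),
                                  seed = 1) {
  mode <- rlang::arg_match(mode)
  assert_scalar_pos(wavelength_deg, "wavelength_deg")
  assert_scalar_pos(speed_dps, "speed_dps")
  scene <- make_grating_scene(wavelength_deg, contrast = contrast,
                              speed_dps = speed_dps,
                              duration_ms = duration_ms)
  pr <- corresponding_pair(eye_pair, "R7", 0, 0)
  pr <- dplyr::filter(pr, .data$eye == "right")
  li <- render_binocular(scene, eye_pair, photoreceptors = pr,
                         kinematics = kinematics, mode = mode)
  v <- bump_response(light_series(li, pr$pr_id), pr_params, seed = seed)
  keep <- v$t_ms >= settle_ms
  x <- v$v[keep] - mean(v$v[keep])
  tt_s <- v$t_ms[keep] / 1000
  f_stim <- abs(speed_dps) / wavelength_deg
  # phase-coherent detection: per-segment lock-in Fourier coefficients at
  # the stimulus frequency (absolute-time phase, so segments are exactly
  # phase-aligned); the SNR is the ratio of the coherent power to the
  # across-segment variance.  A deterministic modulation adds coherently
  # while noise phases are random, so noise alone cannot fake a peak.
  period_ms <- 1000 * wavelength_deg / abs(speed_dps)
  seg_len <- max(64L, as.integer(round(
    max(1, round(200 / period_ms)) * period_ms / scene$dt_ms)))
  k <- max(2L, floor(length(x) / seg_len))
  seg_len <- floor(length(x) / k)
  carrier <- exp(-2i * pi * f_stim * tt_s)
  cj <- vapply(seq_len(k), function(s) {
    idx <- (s - 1) * seg_len + seq_len(seg_len)
    mean(x[idx] * carrier[idx])
  }, complex(1))
  cbar <- mean(cj)
  v_seg <- sum(Mod(cj - cbar)^2) / (k - 1)
  snr <- if (v_seg > 0) {
    max(0, k * Mod(cbar)^2 / v_seg - 1)
  } else {
    Inf
  }
  tibble::tibble(wavelength_deg = wavelength_deg, speed_dps = speed_dps,
                 mode = mode, modulation_snr = snr,
                 resolvable = snr >= threshold, f_stim_hz = f_stim,
                 seed = seed)
}

#' Resolvability sweep over wavelengths and modes
#'
#' @param eye_pair An [build_eye_pair()] result.
#' @param wavelengths_deg Grating wavelengths to test.
#' @param modes Sampling modes.
#' @param ... Passed to [dynamic_resolvability()].
#' @return A `resolvability` tibble, one row per condition.
#' @export
resolvability_sweep <- function(eye_pair,
                                wavelengths_deg = c(1, 2, 3, 4.5, 6, 9),
                                modes = c("static", "microsaccadic"), ...) {
  extra <- list(...)
  conds <- tidyr::crossing(wavelength_deg = wavelengths_deg, mode = modes)
  purrr::pmap_dfr(conds, function(wavelength_deg, mode) {
    do.call(dynamic_resolvability,
            c(list(eye_pair, wavelength_deg, mode = mode), extra))
  })
}

#' Correlator-based optomotor response prediction
#'
#' Predicts the turning (torque) response to a rotating panoramic grating
#' with an array of Hassenstein--Reichardt correlators: neighbouring
#' equatorial photoreceptor signals are rendered through the deterministic
#' pipeline, passed through the phasic LMC stage, and combined pairwise by
#' delay-and-multiply detectors (delayed arm `delay_ms`), summed over both
#' eyes.  Positive output means a syndirectional (normal optomotor)
#' response; the output is odd in yaw velocity.  For hyperacute wavelengths
#' the predicted sign can reverse relative to coarse gratings; the full
#' parameter set is returned with the result.
#'
#' @param eye_pair An [build_eye_pair()] result.
#' @param wavelength_deg Grating wavelength (degrees).
#' @param yaw_dps Yaw rotation speed (deg/s, nonzero).
#' @param mode `"static"` or `"microsaccadic"`.
#' @param n_pairs Correlator pairs per eye.
#' @param delay_ms Delay-arm time constant surrogate (pure delay, ms).
#' @param duration_ms,settle_ms Simulation and discarded transient length.
#' @param kinematics,pr_params Pipeline parameters.
#' @return A one-row `optomotor` tibble with the signed torque proxy and
#'   all parameters.
#' @export
optomotor_response <- function(eye_pair, wavelength_deg, yaw_dps = 30,
                               mode = c("microsaccadic", "static"),
                               n_pairs = 6, delay_ms = 20,
                               duration_ms = 1500, settle_ms = 300,
                               kinematics = kinetics_params(),
                               pr_params = photoreceptor_params()) {
  mode <- rlang::arg_match(mode)
  if (yaw_dps == 0) stop_domain("`yaw_dps` must be nonzero.")
  scene <- make_grating_scene(wavelength_deg, speed_dps = yaw_dps,
                              duration_ms = duration_ms)
  torque <- 0
  for (e in c("left", "right")) {
    omm <- dplyr::filter(eye_pair$ommatidia, .data$eye == e,
                         abs(.data$elevation_deg) < 0.1)
    omm <- dplyr::arrange(omm, .data$azimuth_deg)
    lat <- dplyr::filter(omm, abs(.data$azimuth_deg) >= 15,
                         abs(.data$azimuth_deg) <= 15 + (n_pairs + 1) * 4.6)
    lat <- dplyr::arrange(lat, abs(.data$azimuth_deg))[seq_len(n_pairs + 1), ]
    lat <- dplyr::arrange(lat, .data$azimuth_deg)
    prs <- dplyr::filter(eye_pair$photoreceptors, .data$eye == e,
                         .data$omm_id %in% lat$omm_id, .data$cell == "R7")
    prs <- dplyr::left_join(prs,
                            dplyr::select(lat, "omm_id", ax = "azimuth_deg"),
                            by = "omm_id")
    prs <- dplyr::arrange(prs, .data$ax)
    li <- render_binocular(scene, eye_pair, photoreceptors = prs,
                           kinematics = kinematics, mode = mode)
    sig <- lapply(prs$pr_id, function(id) {
      lmc_transform(adaptive_response(light_series(li, id), pr_params))$v
    })
    d <- max(1L, as.integer(round(delay_ms / scene$dt_ms)))
    keep <- which(li$t_ms >= settle_ms)
    keep <- keep[keep > d]
    for (i in seq_len(length(sig) - 1)) {
      a <- sig[[i]]
      b <- sig[[i + 1]]
      torque <- torque +
        mean(a[keep - d] * b[keep] - a[keep] * b[keep - d])
    }
  }
  tibble::tibble(wavelength_deg = wavelength_deg, yaw_dps = yaw_dps,
                 mode = mode, torque = torque, n_pairs = n_pairs,
                 delay_ms = delay_ms, duration_ms = duration_ms,
                 settle_ms = settle_ms)
}
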