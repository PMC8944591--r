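#' Closed-form binocular disparity of a point at depth
#'
#' Azimuthal difference between the two eyes' projections of a midline
#' point: `2 * atan(k / (2 z))` for baseline `k` and depth `z`.
#'
#' @param depth_mm Depth (mm).
#' @param baseline_mm Inter-eye baseline (mm).
#' @return Disparity in degrees.
#' @export
disparity_deg <- function(depth_mm, baseline_mm = 0.4) {
  2 * rad2deg(atan(baseline_mm / (2 * depth_mm)))
}

#' Per-eye apparent object tracks of a scene
#'
#' Projects each scene object from both eyes' vantage points (eyes at
#' x = +/- baseline/2) over the scene's time base: apparent azimuth,
#' elevation and angular radius.  Objects at finite depth show perspective
#' disparity between the eyes; angular (panoramic) objects do not.
#'
#' @param scene A `scene`.
#' @param baseline_mm Inter-eye baseline (mm).
#' @return A tibble: `t_ms`, `object`, `eye`, `az_deg`, `el_deg`,
#'   `radius_deg`.
#' @export
scene_tracks <- function(scene, baseline_mm = 0.4) {
  tt <- scene_times(scene)
  drift <- object_drift(scene, tt)
  if (!nrow(scene$objects)) {
    return(tibble::tibble(t_ms = double(), object = integer(),
                          eye = character(), az_deg = double(),
                          el_deg = double(), radius_deg = double()))
  }
  purrr::map_dfr(seq_len(nrow(scene$objects)), function(i) {
    ob <- scene$objects[i, ]
    theta <- ob$az_deg + drift
    purrr::map_dfr(c("left", "right"), function(e) {
      ap <- apparent_object(ob, theta, e, baseline_mm)
      tibble::tibble(t_ms = tt, object = i, eye = e,
                     az_deg = ap$az, el_deg = ap$el, radius_deg = ap$rad)
    })
  })
}

# Angular drift (deg) of scene objects over time.
object_drift <- function(scene, tt) {
  if (scene$motion$type %in% c("translate_az", "yaw")) {
    scene$motion$speed_dps * tt / 1000
  } else {
    rep(0, length(tt))
  }
}

# Grating drift (deg) over time: only rigid yaw moves the panorama.
grating_drift <- function(scene, tt) {
  if (scene$motion$type == "yaw") scene$motion$speed_dps * tt / 1000
  else rep(0, length(tt))
}

# Apparent azimuth/elevation/radius of one object (possibly over a vector
# of angular positions theta) from one eye's vantage point.
apparent_object <- function(ob, theta_deg, eye, baseline_mm) {
  if (is.na(ob$z_mm)) {
    return(list(az = theta_deg, el = rep(ob$el_deg, length(theta_deg)),
                rad = rep(ob$diam_deg / 2, length(theta_deg))))
  }
  p <- ob$z_mm * sph_to_cart(theta_deg, ob$el_deg)
  s <- if (eye == "right") 1 else -1
  rel_x <- p[, 1] - s * baseline_mm / 2
  dist <- sqrt(rel_x^2 + p[, 2]^2 + p[, 3]^2)
  r_mm <- ob$z_mm * tan(deg2rad(ob$diam_deg / 2))
  list(
    az = rad2deg(atan2(rel_x, p[, 2])),
    el = rad2deg(asin(p[, 3] / dist)),
    rad = rad2deg(asin(pmin(1, r_mm / dist)))
  )
}

# Precomputed per-eye scene terms shared by all photoreceptors.
scene_precompute <- function(scene, baseline_mm) {
  tt <- scene_times(scene)
  drift <- object_drift(scene, tt)
  dots <- list(left = list(), right = list())
  if (nrow(scene$objects)) {
    for (e in c("left", "right")) {
      dots[[e]] <- lapply(seq_len(nrow(scene$objects)), function(i) {
        ob <- scene$objects[i, ]
        ap <- apparent_object(ob, ob$az_deg + drift, e, baseline_mm)
        loc <- if (!is.null(scene$grating)) {
          grating_value(scene$grating, ob$az_deg, mid = scene$background)
        } else {
          scene$background
        }
        c(ap, list(depth = (loc - ob$reflectance)))
      })
    }
  }
  list(t_ms = tt, n = length(tt), dots = dots,
       g_drift = grating_drift(scene, tt),
       grating = scene$grating, background = scene$background)
}

# Intensity seen by one photoreceptor RF (centre c_az/c_el, FWHM f, fast
# axis fx/fy) displaced by `offsets` and narrowed by `nars`, at time
# indices `idx` (vectorised).
eval_pr_intensity <- function(pre, eye, c_az, c_el, fwhm, fx, fy,
                              offsets, nars, idx) {
  az <- c_az + offsets * fx / cos(deg2rad(c_el))
  el <- c_el + offsets * fy
  sigma <- fwhm_to_sigma(fwhm * (1 - nars))
  val <- if (!is.null(pre$grating)) {
    grating_conv(pre$grating, az, sigma, drift_deg = pre$g_drift[idx],
                 mid = pre$background)
  } else {
    rep(pre$background, length(idx))
  }
  for (dot in pre$dots[[eye]]) {
    d <- ang_dist_deg(az, el, dot$az[idx], dot$el[idx])
    val <- val - dot$depth * gauss_disk_mass(d, dot$rad[idx], sigma)
  }
  pmax(val, 0)
}

# Mean intensity over the ommatidium's eight photoreceptor RFs (the unit's
# total absorption drives its shared mechanical state), at one time index.
eval_unit_drive <- function(pre, eye, c_az, c_el, fwhm, fx, fy,
                            offset, nar, k) {
  az <- c_az + offset * fx / cos(deg2rad(c_el))
  el <- c_el + offset * fy
  sigma <- fwhm_to_sigma(fwhm * (1 - nar))
  val <- if (!is.null(pre$grating)) {
    grating_conv(pre$grating, az, sigma, drift_deg = pre$g_drift[k],
                 mid = pre$background)
  } else {
    rep(pre$background, length(az))
  }
  for (dot in pre$dots[[eye]]) {
    d <- ang_dist_deg(az, el, dot$az[k], dot$el[k])
    val <- val - dot$depth * gauss_disk_mass(d, dot$rad[k], sigma)
  }
  mean(pmax(val, 0))
}

# Closed-loop microsaccade trajectory of one ommatidium: the unit's eight
# RFs (R1-R8 contract as one) sample the scene, their mean light steps the
# kinematics after the mechanical latency, and the moved, narrowed RFs
# sample the next frame.  State starts at the fixed point of the first
# frame.
drive_trajectory <- function(pre, eye, cells, fx, fy, kin, dt) {
  n <- pre$n
  nmx <- kin$narrow_max
  amx <- kin$a_max_deg
  c_az <- cells$rf_az_deg
  c_el <- cells$rf_el_deg
  fwhm <- cells$fwhm_deg
  lag <- max(1L, as.integer(round(kin$latency_ms / dt)))
  i0 <- eval_unit_drive(pre, eye, c_az, c_el, fwhm, fx, fy, 0, 0, 1L)
  st <- kin_init(i0, kin)
  for (iter in 1:3) {
    i0 <- eval_unit_drive(pre, eye, c_az, c_el, fwhm, fx, fy,
                          st$offset, nmx * st$offset / amx, 1L)
    st <- kin_init(i0, kin)
  }
  off <- gain <- numeric(n)
  i_meas <- numeric(n)
  off[1] <- st$offset
  gain[1] <- st$gain
  i_meas[1] <- i0
  if (n > 1) {
    for (k in 2:n) {
      st <- kin_step(st, i_meas[max(1L, k - lag)], kin, dt)
      off[k] <- st$offset
      gain[k] <- st$gain
      i_meas[k] <- eval_unit_drive(pre, eye, c_az, c_el, fwhm, fx, fy,
                                   off[k], nmx * off[k] / amx, k)
    }
  }
  tibble::tibble(t_ms = pre$t_ms, offset_deg = off,
                 narrowing = nmx * off / amx, gain = gain,
                 drive_intensity = i_meas)
}

#' Render a scene into binocular photoreceptor light inputs
#'
#' Integrates the scene radiance over every selected photoreceptor's
#' (possibly moving and narrowing) Gaussian receptive field, from each
#' eye's own vantage point, over the scene's time base.  In
#' `"microsaccadic"` mode rendering and kinematics run in closed loop: each
#' ommatidium's sampled light drives its shared microsaccade state (one
#' state per ommatidium, since the R1--R8 of an ommatidium contract as a
#' unit), the state displaces and narrows the RFs, and the moved RFs sample
#' the next frame.  `"static"` freezes all RFs at rest; `"asynchronous"`
#' delays one eye's sampling by `phase_ms` (kinematic state and
#' transduction timeline shift together, so the two eyes no longer sample
#' the scene simultaneously); `"asymmetric"` keeps one eye static while the
#' other saccades; `"monocular"` zeroes the non-selected eye's output.
#'
#' @param phase_ms Sampling delay of `delayed_eye` in asynchronous mode.
#' @param scene A `scene`.
#' @param eye_pair An [build_eye_pair()] result.
#' @param photoreceptors A subset of `eye_pair$photoreceptors` to render
#'   (default: all cells with RF centres within 12 degrees of straight
#'   ahead).
#' @param kinematics A [kinetics_params()].
#' @param mode Sampling mode, see above.
#' @param delayed_eye,static_eye,side Eye selectors for the asynchronous,
#'   asymmetric and monocular modes (`side` is the eye that keeps seeing).
#' @param noise_photons_per_ms If non-NULL, applies Poisson photon noise to
#'   the rendered intensities at this mean photon count per photoreceptor
#'   per millisecond at luminance 1.
#' @param seed Seed for the Poisson noise (also recorded when unused, so a
#'   pipeline seed can be threaded through).
#' @return An object of class `light_input`: time base, an intensity matrix
#'   (time x photoreceptor), the photoreceptor metadata, and the per-
#'   ommatidium saccade-state trajectories.
#' @export
render_binocular <- function(scene, eye_pair,
                             photoreceptors = NULL,
                             kinematics = kinetics_params(),
                             mode = c("microsaccadic", "static",
                                      "asynchronous", "asymmetric",
                                      "monocular"),
                             phase_ms = 20,
                             delayed_eye = "right",
                             static_eye = "right",
                             side = "left",
                             noise_photons_per_ms = NULL,
                             seed = NULL) {
  mode <- rlang::arg_match(mode)
  if (mode == "monocular" && !side %in% c("left", "right")) {
    stop_domain("`side` must be \"left\" or \"right\" (one eye must see).")
  }
  pr <- photoreceptors %||%
    dplyr::filter(eye_pair$photoreceptors,
                  ang_dist_deg(.data$rf_az_deg, .data$rf_el_deg, 0, 0) <= 12)
  if (!nrow(pr)) stop_domain("No photoreceptors selected for rendering.")
  axes <- dplyr::select(eye_pair$ommatidia, "eye", "omm_id",
                        ax_az = "azimuth_deg", ax_el = "elevation_deg")
  pr <- dplyr::left_join(pr, axes, by = c("eye", "omm_id"))
  pre <- scene_precompute(scene, eye_pair$config$baseline_mm)
  dt <- scene$dt_ms
  if (mode != "static" && dt > 1 + 1e-9) {
    stop_domain("Kinematic rendering needs a frame interval <= 1 ms.")
  }
  n <- pre$n
  groups <- dplyr::distinct(pr, .data$eye, .data$omm_id,
                            .data$ax_az, .data$ax_el,
                            .data$fast_az, .data$fast_el)
  states <- vector("list", nrow(groups))
  names(states) <- paste(groups$eye, groups$omm_id, sep = ":")
  intensity <- matrix(0, n, nrow(pr))
  colnames(intensity) <- as.character(pr$pr_id)

  for (g in seq_len(nrow(groups))) {
    gr <- groups[g, ]
    eye_static <- mode == "static" ||
      (mode == "asymmetric" && gr$eye == static_eye)
    st <- if (eye_static) {
      tibble::tibble(t_ms = pre$t_ms, offset_deg = 0, narrowing = 0,
                     gain = 1, drive_intensity = NA_real_)
    } else {
      unit_cells <- dplyr::filter(eye_pair$photoreceptors,
                                  .data$eye == gr$eye,
                                  .data$omm_id == gr$omm_id)
      drive_trajectory(pre, gr$eye, unit_cells, gr$fast_az, gr$fast_el,
                       kinematics, dt)
    }
    states[[g]] <- st
    members <- which(pr$eye == gr$eye & pr$omm_id == gr$omm_id)
    for (m in members) {
      intensity[, m] <- eval_pr_intensity(
        pre, pr$eye[m], pr$rf_az_deg[m], pr$rf_el_deg[m], pr$fwhm_deg[m],
        gr$fast_az, gr$fast_el, st$offset_deg, st$narrowing, seq_len(n)
      )
    }
  }
  if (mode == "asynchronous") {
    # the delayed eye samples the world phase_ms late: its kinematic state
    # and transduction timeline shift together, so the two eyes' samples of
    # any scene moment are no longer simultaneous
    sh <- as.integer(round(phase_ms / dt))
    lagix <- pmax(1L, seq_len(n) - sh)
    del <- pr$eye == delayed_eye
    intensity[, del] <- intensity[lagix, del]
  }
  if (mode == "monocular") {
    intensity[, pr$eye != side] <- 0
  }
  if (!is.null(noise_photons_per_ms)) {
    if (!is.null(seed)) set.seed(seed)
    q <- noise_photons_per_ms * dt
    intensity[] <- stats::rpois(length(intensity), intensity * q) / q
  }
  structure(
    list(
      t_ms = pre$t_ms,
      intensity = intensity,
      photoreceptors = dplyr::select(pr, "pr_id", "eye", "omm_id", "cell",
                                     "rf_az_deg", "rf_el_deg", "fwhm_deg"),
      states = states,
      mode = mode,
      dt_ms = dt,
      seed = seed
    ),
    class = "light_input"
  )
}

#' @export
print.light_input <- function(x, ...) {
  cat("<light_input>\n")
  cat(sprintf("  %d photoreceptors x %d frames (%.2g ms), mode %s\n",
              ncol(x$intensity), length(x$t_ms), x$dt_ms, x$mode))
  invisible(x)
}

#' Tidy a rendered light input
#'
#' @param x A `light_input`.
#' @param ... Unused.
#' @return A long tibble: `t_ms`, `pr_id`, `eye`, `cell`, `intensity`.
#' @export
as_tibble.light_input <- function(x, ...) {
  long <- tibble::as_tibble(x$intensity)
  long$t_ms <- x$t_ms
  long <- tidyr::pivot_longer(long, -"t_ms", names_to = "pr_id",
                              values_to = "intensity")
  long$pr_id <- as.integer(long$pr_id)
  dplyr::left_join(
    long,
    dplyr::select(x$photoreceptors, "pr_id", "eye", "cell"),
    by = "pr_id"
  )
}

# Extract one photoreceptor's intensity series from a light_input.
light_series <- function(li, pr_id) {
  li$intensity[, as.character(pr_id)]
}

#' Write a light input or voltage response as CSV + JSON metadata
#'
#' Stores the time series as a plain CSV (one column per photoreceptor) and
#' a JSON sidecar with ids, eye labels, mode and seed.
#'
#' @param x A `light_input` or `voltage_response`.
#' @param path Base path without extension; writes `<path>.csv` and
#'   `<path>.json`.
#' @return `path`, invisibly.
#' @export
write_timeseries <- function(x, path) {
  if (inherits(x, "light_input")) {
    df <- tibble::as_tibble(x$intensity)
    df <- dplyr::mutate(df, t_ms = x$t_ms, .before = 1)
    meta <- list(kind = "light_input", mode = x$mode, dt_ms = x$dt_ms,
                 seed = x$seed, photoreceptors = x$photoreceptors)
  } else {
    df <- tibble::tibble(t_ms = x$t_ms, v = x$v)
    meta <- list(kind = "voltage_response", stage = attr(x, "stage"),
                 seed = attr(x, "seed"))
  }
  readr::write_csv(df, paste0(path, ".csv"))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, dataframe = "columns")
  invisible(path)
}
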