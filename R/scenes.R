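#' Synthetic scene descriptions
#'
#' Scenes are parametric: a uniform background, optional dark/bright dots
#' (angular objects on the panorama or physical disks at a finite depth in
#' front of the head) and an optional square-wave stripe grating, plus a
#' rigid motion (azimuthal object translation at constant depth, or yaw
#' rotation of the panorama).  Luminances are normalised to `[0, 1]` and the
#' time base must be at most 1 ms for compatibility with the microsaccade
#' kinematics.
#'
#' @name scene
NULL

new_scene <- function(objects, grating = NULL, background = 1,
                      motion = list(type = "none", speed_dps = 0),
                      duration_ms = 500, dt_ms = 1, control = NULL) {
  if (background < 0 || background > 1) {
    stop_domain("`background` must lie in [0, 1].")
  }
  if (dt_ms > 1 + 1e-9) stop_domain("`dt_ms` must be <= 1 ms.")
  structure(
    list(objects = objects, grating = grating, background = background,
         motion = motion, duration_ms = duration_ms, dt_ms = dt_ms,
         control = control),
    class = "scene"
  )
}

#' @export
print.scene <- function(x, ...) {
  cat("<scene>\n")
  cat(sprintf("  %d object(s)%s; background %.2f; motion %s %.1f deg/s; %d ms @ %.2g ms\n",
              nrow(x$objects),
              if (!is.null(x$grating))
                sprintf(" + grating (%.3g deg wavelength)", x$grating$wavelength_deg)
              else "",
              x$background, x$motion$type, x$motion$speed_dps,
              x$duration_ms, x$dt_ms))
  invisible(x)
}

scene_times <- function(scene) seq(0, scene$duration_ms, by = scene$dt_ms)

#' Moving dot-pair scene
#'
#' Two dark dots a fixed angular distance apart, travelling left to right
#' at constant angular speed on a circle of constant depth in the equatorial
#' plane, seen against a bright background.  The defaults follow the
#' binocular depth experiments: dots 3.5 degrees apart moving at 50 deg/s,
#' 25 mm from the eyes.
#'
#' @param separation_deg Centre-to-centre angular separation (degrees).
#' @param speed_dps Angular speed (deg/s); positive moves toward +azimuth.
#' @param depth_mm Object distance from the head centre (mm).
#' @param dot_deg Angular dot diameter as seen from the head centre.
#' @param start_az_deg Initial azimuth of the leading dot.
#' @param background Background luminance.
#' @param reflectance Dot luminance.
#' @param duration_ms Scene duration; the default lets the trailing dot
#'   traverse to the mirror-image azimuth of the start.
#' @param dt_ms Frame interval (ms).
#' @return A `scene`.
#' @export
make_dot_pair <- function(separation_deg = 3.5, speed_dps = 50,
                          depth_mm = 25, dot_deg = 1.7,
                          start_az_deg = -15, background = 1,
                          reflectance = 0, duration_ms = NULL, dt_ms = 1) {
  assert_scalar_pos(separation_deg, "separation_deg")
  assert_scalar_pos(depth_mm, "depth_mm")
  if (speed_dps < 0) stop_domain("`speed_dps` must be >= 0 (use start azimuth to flip).")
  duration_ms <- duration_ms %||%
    (if (speed_dps > 0)
      1000 * (2 * abs(start_az_deg) + separation_deg) / speed_dps
     else 500)
  objects <- tibble::tibble(
    type = "dot",
    az_deg = c(start_az_deg, start_az_deg - separation_deg),
    el_deg = 0,
    z_mm = depth_mm,
    diam_deg = dot_deg,
    reflectance = reflectance
  )
  new_scene(objects, background = background,
            motion = list(type = "translate_az", speed_dps = speed_dps),
            duration_ms = duration_ms, dt_ms = dt_ms)
}

#' Hidden-dot stripe scene
#'
#' A static panoramic black/white square-wave stripe pattern with a single
#' black dot superposed on the centre of a white stripe ("hidden", because
#' the dot is finer than the ommatidial pixelation).  The matching dotless
#' control scene is attached as `$control`.
#'
#' @param dot_deg Dot diameter (degrees).
#' @param stripe_deg Stripe width (degrees); the grating wavelength is twice
#'   this.
#' @param dot_az_deg,dot_el_deg Dot position; the stripe phase is aligned so
#'   that a white stripe is centred on the dot azimuth.
#' @param contrast Stripe Michelson-like contrast (1 = full black/white).
#' @return A `scene` (static) with the control scene in `$control`.
#' @export
make_hidden_dot_scene <- function(dot_deg = 0.98, stripe_deg = 1.2,
                                  dot_az_deg = 0, dot_el_deg = 0,
                                  contrast = 1) {
  assert_scalar_pos(dot_deg, "dot_deg")
  assert_scalar_pos(stripe_deg, "stripe_deg")
  grating <- list(wavelength_deg = 2 * stripe_deg, contrast = contrast,
                  phase_deg = dot_az_deg)
  control <- new_scene(
    objects = tibble::tibble(type = character(), az_deg = double(),
                             el_deg = double(), z_mm = double(),
                             diam_deg = double(), reflectance = double()),
    grating = grating, background = 0.5,
    duration_ms = 100, dt_ms = 1
  )
  dot <- tibble::tibble(type = "dot", az_deg = dot_az_deg, el_deg = dot_el_deg,
                        z_mm = NA_real_, diam_deg = dot_deg, reflectance = 0)
  new_scene(dot, grating = grating, background = 0.5,
            duration_ms = 100, dt_ms = 1, control = control)
}

#' Drifting or rotating grating scene
#'
#' A panoramic vertical square-wave grating, drifting at a constant angular
#' speed (equivalently, a yaw rotation of the panorama).
#'
#' @param wavelength_deg Spatial wavelength (degrees per black+white cycle).
#' @param contrast Contrast in `[0, 1]`.
#' @param speed_dps Drift speed (deg/s); sign gives the direction.
#' @param duration_ms,dt_ms Time base.
#' @return A `scene`.
#' @export
make_grating_scene <- function(wavelength_deg, contrast = 1, speed_dps = 50,
                               duration_ms = 3000, dt_ms = 1) {
  assert_scalar_pos(wavelength_deg, "wavelength_deg")
  if (contrast < 0 || contrast > 1) stop_domain("`contrast` must lie in [0, 1].")
  new_scene(
    objects = tibble::tibble(type = character(), az_deg = double(),
                             el_deg = double(), z_mm = double(),
                             diam_deg = double(), reflectance = double()),
    grating = list(wavelength_deg = wavelength_deg, contrast = contrast,
                   phase_deg = 0),
    background = 0.5,
    motion = list(type = "yaw", speed_dps = speed_dps),
    duration_ms = duration_ms, dt_ms = dt_ms
  )
}

#' Mirror a scene about the sagittal plane
#'
#' Negates all object azimuths, the grating phase and the motion direction.
#' Rendering a mirrored scene with swapped eyes reproduces the original
#' rendering with eye labels exchanged, bit for bit.
#'
#' @param scene A `scene`.
#' @return The mirrored `scene`.
#' @export
mirror_scene <- function(scene) {
  scene$objects$az_deg <- -scene$objects$az_deg
  if (!is.null(scene$grating)) scene$grating$phase_deg <- -scene$grating$phase_deg
  scene$motion$speed_dps <- -scene$motion$speed_dps
  if (!is.null(scene$control)) scene$control <- mirror_scene(scene$control)
  scene
}

#' Metric dot diameters implied by a scene
#'
#' For fixed angular size, the physical dot diameter scales linearly with
#' depth (similar triangles).
#'
#' @param scene A `scene`.
#' @return Numeric vector of metric diameters (mm; `NA` for angular objects).
#' @export
dot_metric_diameter <- function(scene) {
  with(scene$objects, 2 * z_mm * tan(deg2rad(diam_deg / 2)))
}

# Unconvolved square-wave grating luminance at azimuth x (deg), around
# mid-level `mid`.
grating_value <- function(grating, x_deg, drift_deg = 0, mid = 0.5) {
  mid + 0.5 * grating$contrast *
    sign(cos(2 * pi * (x_deg - grating$phase_deg - drift_deg) /
               grating$wavelength_deg))
}

# Gaussian-convolved square-wave grating (1D, vertical stripes): Fourier
# series with per-harmonic Gaussian attenuation.
grating_conv <- function(grating, x_deg, sigma_deg, drift_deg = 0,
                         mid = 0.5) {
  lam <- grating$wavelength_deg
  val <- 0 * x_deg
  for (k in seq(1, 41, by = 2)) {
    att <- exp(-2 * pi^2 * sigma_deg^2 * k^2 / lam^2)
    if (all(att < 1e-14)) break
    sgn <- if (((k - 1) / 2) %% 2 == 0) 1 else -1
    val <- val + sgn * att / k *
      cos(2 * pi * k * (x_deg - grating$phase_deg - drift_deg) / lam)
  }
  mid + 0.5 * grating$contrast * (4 / pi) * val
}

#' Rasterise a static scene to a luminance matrix
#'
#' Samples the unblurred scene luminance on a regular azimuth x elevation
#' grid (rows = elevation, columns = azimuth).  Used by the static acuity
#' analyses.
#'
#' @param scene A static `scene`.
#' @param az_range,el_range Extents `c(min, max)` in degrees.
#' @param grid_deg Sample spacing (degrees).
#' @return A matrix with attributes `az` and `el` (the sample coordinates).
#' @export
raster_scene <- function(scene, az_range = c(-12, 12), el_range = c(-12, 12),
                         grid_deg = 0.05) {
  az <- seq(az_range[1], az_range[2], by = grid_deg)
  el <- seq(el_range[1], el_range[2], by = grid_deg)
  base <- if (!is.null(scene$grating)) {
    grating_value(scene$grating, az, mid = scene$background)
  } else {
    rep(scene$background, length(az))
  }
  m <- matrix(base, nrow = length(el), ncol = length(az), byrow = TRUE)
  if (nrow(scene$objects)) {
    for (i in seq_len(nrow(scene$objects))) {
      ob <- scene$objects[i, ]
      r <- ob$diam_deg / 2
      in_dot <- outer(el - ob$el_deg, az - ob$az_deg,
                      function(de, da) de^2 + da^2 <= r^2)
      m[in_dot] <- ob$reflectance
    }
  }
  attr(m, "az") <- az
  attr(m, "el") <- el
  m
}
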