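# Shared angular / numerical helpers. Angles are degrees in the user-facing
# API; conversions happen at the trigonometry boundary.

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

#' @keywords internal
#' @noRd
fwhm_to_sigma <- function(fwhm) fwhm / (2 * sqrt(2 * log(2)))

# Head-centric spherical -> cartesian unit vector.
# Azimuth positive to the animal's right, elevation positive dorsal;
# (0, 0) is straight ahead (+y), x points right, z points up.
sph_to_cart <- function(az_deg, el_deg) {
  az <- deg2rad(az_deg)
  el <- deg2rad(el_deg)
  cbind(x = sin(az) * cos(el), y = cos(az) * cos(el), z = sin(el))
}

cart_to_sph <- function(v) {
  v <- matrix(v, ncol = 3)
  n <- sqrt(rowSums(v^2))
  list(
    az_deg = rad2deg(atan2(v[, 1], v[, 2])),
    el_deg = rad2deg(asin(pmin(1, pmax(-1, v[, 3] / n))))
  )
}

# Great-circle distance between directions, degrees.  Written with
# cos(az1 - az2) so that the result is exactly invariant under a global
# azimuth sign flip (mirror tests rely on bitwise symmetry).
ang_dist_deg <- function(az1, el1, az2, el2) {
  a1 <- deg2rad(el1); a2 <- deg2rad(el2)
  dl <- deg2rad(az1 - az2)
  c_ang <- sin(a1) * sin(a2) + cos(a1) * cos(a2) * cos(dl)
  rad2deg(acos(pmin(1, pmax(-1, c_ang))))
}

# Local tangent basis at (az, el): e_az along increasing azimuth,
# e_el along increasing elevation; both unit, orthogonal to the radial.
tangent_basis <- function(az_deg, el_deg) {
  az <- deg2rad(az_deg); el <- deg2rad(el_deg)
  list(
    e_az = cbind(cos(az), -sin(az), 0 * az),
    e_el = cbind(-sin(az) * sin(el), -cos(az) * sin(el), cos(el))
  )
}

# Integral of a unit-mass circular Gaussian (sd sigma) over a disk of
# radius r whose centre lies at distance d from the Gaussian centre.
# Exact via the noncentral chi-squared cdf with 2 df.
gauss_disk_mass <- function(d, r, sigma) {
  stats::pchisq((r / sigma)^2, df = 2, ncp = (d / sigma)^2)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_domain <- function(msg, ...) {
  rlang::abort(msg, class = "saccadeye_domain_error", ...)
}

assert_scalar_pos <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1 || !is.finite(x) || x <= 0) {
    stop_domain(sprintf("`%s` must be a single positive finite number.", name))
  }
  invisible(x)
}
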