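#' Photomechanical microsaccade kinetics parameters
#'
#' Parameters of the two-phase receptive-field movement triggered by light
#' changes: after a short latency a brightening step contracts the
#' photoreceptors (fast phase, completing within tens of milliseconds) and
#' darkening lets them relax back over several hundred milliseconds, with
#' full relaxation inside a second.  The displacement amplitude saturates
#' with intensity following Michaelis--Menten kinetics, the RF narrows in
#' proportion to its displacement, and the amplitude adapts to repeated
#' contrast changes.
#'
#' @param latency_ms Onset latency of the mechanical response (ms); the
#'   movement begins less than 10 ms after a light change.
#' @param tau_act_on_ms,tau_act_off_ms Rise and decay time constants (ms) of
#'   the mechanical activation that drives the contraction (the activation
#'   outlasts a brief flash, so a 10 ms flash still yields a contraction
#'   peaking 40--50 ms after onset).
#' @param tau_fast_ms Fast-phase (contraction) time constant (ms).
#' @param tau_slow_ms Slow-phase (relaxation) time constant (ms); must
#'   exceed `tau_fast_ms`.
#' @param a_max_deg Maximal RF displacement (degrees of visual angle).
#' @param i50 Half-saturation intensity of the amplitude law (stimulus
#'   luminance normalised to `[0, 1]`).
#' @param narrow_max Maximal fractional FWHM reduction, in `[0, 1)`;
#'   narrowing tracks `offset / a_max_deg` proportionally.
#' @param adapt_tau_ms Recovery time constant of amplitude adaptation (ms).
#' @param adapt_strength Fractional gain decrement per unit positive
#'   intensity step (dimensionless).
#' @return A list of class `kinetics_params`.
#' @export
kinetics_params <- function(latency_ms = 8,
                            tau_act_on_ms = 5,
                            tau_act_off_ms = 60,
                            tau_fast_ms = 20,
                            tau_slow_ms = 300,
                            a_max_deg = 2,
                            i50 = 0.1,
                            narrow_max = 0.7,
                            adapt_tau_ms = 500,
                            adapt_strength = 0.5) {
  for (nm in c("latency_ms", "tau_act_on_ms", "tau_act_off_ms", "tau_fast_ms",
               "tau_slow_ms", "a_max_deg", "i50", "adapt_tau_ms")) {
    assert_scalar_pos(get(nm), nm)
  }
  if (tau_slow_ms <= tau_fast_ms) {
    stop_domain("`tau_slow_ms` must exceed `tau_fast_ms`.")
  }
  if (narrow_max < 0 || narrow_max >= 1) {
    stop_domain("`narrow_max` must lie in [0, 1).")
  }
  structure(
    list(latency_ms = latency_ms, tau_act_on_ms = tau_act_on_ms,
         tau_act_off_ms = tau_act_off_ms, tau_fast_ms = tau_fast_ms,
         tau_slow_ms = tau_slow_ms, a_max_deg = a_max_deg, i50 = i50,
         narrow_max = narrow_max, adapt_tau_ms = adapt_tau_ms,
         adapt_strength = adapt_strength),
    class = "kinetics_params"
  )
}

#' Saturating microsaccade amplitude law
#'
#' Michaelis--Menten dependence of the RF displacement amplitude on stimulus
#' intensity: `a_max * I / (I + i50)`.  Monotone nondecreasing, zero in
#' darkness, half-maximal at `I = i50`, saturating at `a_max`.
#'
#' @param intensity Nonnegative intensity (normalised luminance).
#' @param params A [kinetics_params()].
#' @return Displacement amplitude (degrees), vectorised over `intensity`.
#' @export
saccade_amplitude <- function(intensity, params = kinetics_params()) {
  if (any(intensity < 0)) stop_domain("`intensity` must be nonnegative.")
  params$a_max_deg * intensity / (intensity + params$i50)
}

# Internal kinematic state stepping, shared between rf_trajectory() and the
# closed-loop renderer so both integrate identically (explicit Euler, one
# update per frame).
kin_init <- function(i0, params) {
  amp <- saccade_amplitude(i0, params)
  list(gain = 1, act = amp, offset = amp, i_prev = i0)
}

kin_step <- function(st, i_del, params, dt) {
  # adaptation follows the evoked mechanical drive (the saturating
  # amplitude law), so stronger flashes never yield smaller contractions
  da <- (saccade_amplitude(i_del, params) -
           saccade_amplitude(st$i_prev, params)) / params$a_max_deg
  gain <- st$gain * exp(-params$adapt_strength * max(da, 0))
  gain <- gain + (1 - gain) * dt / params$adapt_tau_ms
  target <- gain * saccade_amplitude(i_del, params)
  tau_a <- if (target > st$act) params$tau_act_on_ms else params$tau_act_off_ms
  act <- st$act + (target - st$act) * dt / tau_a
  tau_o <- if (act > st$offset) params$tau_fast_ms else params$tau_slow_ms
  offset <- st$offset + (act - st$offset) * dt / tau_o
  list(gain = gain, act = act, offset = offset, i_prev = i_del)
}

#' Microsaccade trajectory from a light time series
#'
#' Integrates the two-phase kinematic model: intensity (delayed by the
#' onset latency) sets a Michaelis--Menten displacement target scaled by an
#' adapting gain; a mechanical activation stage follows the target with
#' fast rise and slower decay; the RF offset follows the activation with
#' the fast time constant while contracting and the slow one while
#' relaxing.  Narrowing is proportional to the instantaneous offset.
#' The state is initialised at the steady state of the first sample, so a
#' trajectory starting in darkness starts at zero offset.
#'
#' @param light Either a numeric intensity vector (with `dt_ms`) or a data
#'   frame with columns `t_ms` and `intensity` on a uniform time base of at
#'   most 1 ms.
#' @param params A [kinetics_params()].
#' @param dt_ms Sampling interval (ms) when `light` is a bare vector.
#' @param seed Unused by the deterministic kinematics; accepted so callers
#'   can thread one seed through a pipeline.
#' @return A `saccade_state` tibble: `t_ms`, `offset_deg`, `narrowing`,
#'   `gain`, with `params` attached as an attribute.
#' @export
rf_trajectory <- function(light, params = kinetics_params(), dt_ms = 1,
                          seed = NULL) {
  if (is.data.frame(light)) {
    tt <- light$t_ms
    ii <- light$intensity
    if (length(tt) > 1) {
      dts <- diff(tt)
      if (max(abs(dts - dts[1])) > 1e-9) {
        stop_domain("`light` must be on a uniform time base.")
      }
      dt_ms <- dts[1]
    }
  } else {
    ii <- as.numeric(light)
    tt <- (seq_along(ii) - 1) * dt_ms
  }
  if (dt_ms > 1 + 1e-9) stop_domain("Sampling interval must be <= 1 ms.")
  if (any(ii < 0)) stop_domain("Intensities must be nonnegative.")
  lag <- round(params$latency_ms / dt_ms)
  i_del <- c(rep(ii[1], min(lag, length(ii))), ii)[seq_along(ii)]
  st <- kin_init(i_del[1], params)
  n <- length(ii)
  offset <- gain <- numeric(n)
  offset[1] <- st$offset
  gain[1] <- st$gain
  if (n > 1) {
    for (k in 2:n) {
      st <- kin_step(st, i_del[k], params, dt_ms)
      offset[k] <- st$offset
      gain[k] <- st$gain
    }
  }
  out <- tibble::tibble(
    t_ms = tt,
    offset_deg = offset,
    narrowing = params$narrow_max * offset / params$a_max_deg,
    gain = gain
  )
  structure(out, params = params, class = c("saccade_state", class(out)))
}

#' Gaussian receptive field
#'
#' A circular Gaussian angular sensitivity profile with a movement axis.
#' The profile is normalised to unit integral over the (locally flat)
#' visual field.
#'
#' @param center_az_deg,center_el_deg RF centre direction (degrees).
#' @param fwhm_deg Full width at half maximum (degrees).
#' @param fast_az,fast_el Unit tangent vector of the fast-phase RF motion
#'   direction in visual space (the rhabdomere itself moves along the
#'   opposite axis; the ommatidial lens inverts the motion).
#' @return A list of class `receptive_field`.
#' @export
receptive_field <- function(center_az_deg = 0, center_el_deg = 0,
                            fwhm_deg = 5.4, fast_az = 1, fast_el = 0) {
  assert_scalar_pos(fwhm_deg, "fwhm_deg")
  nv <- sqrt(fast_az^2 + fast_el^2)
  structure(
    list(center_az_deg = center_az_deg, center_el_deg = center_el_deg,
         fwhm_deg = fwhm_deg, fast_az = fast_az / nv, fast_el = fast_el / nv),
    class = "receptive_field"
  )
}

#' Displace and narrow a receptive field by a microsaccade state
#'
#' Shifts the RF centre by the instantaneous offset along the fast-phase
#' visual-space axis and scales its FWHM by `1 - narrowing`; the profile
#' stays normalised to unit integral.  With zero offset this is the
#' identity.
#'
#' @param rf A [receptive_field()].
#' @param state A `saccade_state` from [rf_trajectory()].
#' @param t_ms Time (ms) within the state's range.
#' @return A displaced/narrowed `receptive_field`.
#' @export
apply_saccade <- function(rf, state, t_ms) {
  if (t_ms < min(state$t_ms) || t_ms > max(state$t_ms)) {
    stop_domain("`t_ms` lies outside the state's time range.")
  }
  off <- stats::approx(state$t_ms, state$offset_deg, xout = t_ms)$y
  nar <- stats::approx(state$t_ms, state$narrowing, xout = t_ms)$y
  rf$center_az_deg <- rf$center_az_deg +
    off * rf$fast_az / cos(deg2rad(rf$center_el_deg))
  rf$center_el_deg <- rf$center_el_deg + off * rf$fast_el
  rf$fwhm_deg <- rf$fwhm_deg * (1 - nar)
  rf
}

#' Evaluate a receptive-field profile
#'
#' Unit-integral circular Gaussian sensitivity (per square degree) at the
#' given directions, using the locally flat tangent approximation.
#'
#' @param rf A [receptive_field()].
#' @param az_deg,el_deg Directions to evaluate (degrees).
#' @return Sensitivity values.
#' @export
rf_profile <- function(rf, az_deg, el_deg) {
  sigma <- fwhm_to_sigma(rf$fwhm_deg)
  dx <- (az_deg - rf$center_az_deg) * cos(deg2rad(rf$center_el_deg))
  dy <- el_deg - rf$center_el_deg
  exp(-(dx^2 + dy^2) / (2 * sigma^2)) / (2 * pi * sigma^2)
}
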