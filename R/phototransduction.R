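#' Photoreceptor model parameters
#'
#' Parameters of the stochastic quantum-bump phototransduction model: a
#' population of microvilli absorbs photons as independent inhomogeneous
#' Poisson processes; each absorption outside a refractory period produces
#' one stereotyped bump (gamma-shaped kernel) with a jittered latency, and
#' the summed bump train passes through a saturating (Naka--Rushton)
#' nonlinearity.
#'
#' @param n_microvilli Number of transduction units.
#' @param photons_per_ms Mean photon arrival rate at luminance 1
#'   (photons per photoreceptor per ms).
#' @param bump_amplitude Peak amplitude of a single bump (arbitrary units).
#' @param bump_t_peak_ms Bump time to peak (ms).
#' @param bump_shape Gamma shape of the bump kernel.
#' @param refractory_mean_ms,refractory_jitter_ms Mean and spread of the
#'   per-event refractory period (clipped normal, minimum 1 ms).
#' @param latency_jitter_ms Standard deviation of the per-bump latency
#'   jitter (ms).
#' @param dark_noise_rate Spontaneous event rate in darkness (events/s).
#' @param v_max Response ceiling of the saturating nonlinearity.
#' @param s50_frac Half-saturation point of the nonlinearity, as a fraction
#'   of the expected steady bump sum at luminance 1 (ignoring refractory
#'   losses).
#' @return A list of class `pr_params` (with the bump-kernel integral and
#'   derived half-saturation constant attached).
#' @export
photoreceptor_params <- function(n_microvilli = 30000,
                                 photons_per_ms = 1000,
                                 bump_amplitude = 1,
                                 bump_t_peak_ms = 12,
                                 bump_shape = 3,
                                 refractory_mean_ms = 50,
                                 refractory_jitter_ms = 15,
                                 latency_jitter_ms = 2,
                                 dark_noise_rate = 0,
                                 v_max = 1,
                                 s50_frac = 0.5) {
  for (nm in c("n_microvilli", "photons_per_ms", "bump_amplitude",
               "bump_t_peak_ms", "bump_shape", "refractory_mean_ms", "v_max")) {
    assert_scalar_pos(get(nm), nm)
  }
  p <- list(n_microvilli = as.integer(n_microvilli),
            photons_per_ms = photons_per_ms,
            bump_amplitude = bump_amplitude,
            bump_t_peak_ms = bump_t_peak_ms,
            bump_shape = bump_shape,
            refractory_mean_ms = refractory_mean_ms,
            refractory_jitter_ms = refractory_jitter_ms,
            latency_jitter_ms = latency_jitter_ms,
            dark_noise_rate = dark_noise_rate,
            v_max = v_max, s50_frac = s50_frac)
  kt <- bump_kernel(p, dt = 0.1)
  p$kernel_integral_ms <- sum(kt) * 0.1
  p$s50 <- s50_frac * photons_per_ms * p$kernel_integral_ms
  class(p) <- "pr_params"
  p
}

# Gamma bump kernel sampled at dt, unit peak amplitude times bump_amplitude.
bump_kernel <- function(params, dt) {
  s <- params$bump_shape
  th <- params$bump_t_peak_ms / (s - 1)
  tmax <- params$bump_t_peak_ms + 8 * th
  tt <- seq(dt, tmax, by = dt)
  k <- (tt / params$bump_t_peak_ms)^(s - 1) *
    exp((params$bump_t_peak_ms - tt) / th)
  params$bump_amplitude * k
}

new_voltage_response <- function(t_ms, v, stage, seed = NULL, ...) {
  out <- tibble::tibble(t_ms = t_ms, v = v)
  structure(out, stage = stage, seed = seed, ...,
            class = c("voltage_response", class(out)))
}

#' @export
print.voltage_response <- function(x, ...) {
  cat(sprintf("<voltage_response> stage %s, %d samples\n",
              attr(x, "stage"), nrow(x)))
  NextMethod()
}

# Causal convolution of a binned event train with the bump kernel.
conv_causal <- function(x, kern) {
  n <- length(x)
  y <- stats::convolve(c(x, numeric(length(kern))), rev(kern), type = "open")
  y[seq_len(n)]
}

naka_rushton <- function(raw, params) {
  params$v_max * raw / (raw + params$s50)
}

#' Stochastic quantum-bump response to a light series
#'
#' Draws photon arrivals per frame from a Poisson law, distributes them over
#' the microvilli, rejects absorptions into refractory units, and convolves
#' the accepted (latency-jittered) bump train with the gamma bump kernel
#' before the saturating nonlinearity.  Bookkeeping is exact: delivered
#' photons minus refractory losses equals the bump count, and identical
#' seeds give identical output.
#'
#' @param light Nonnegative luminance series in `[0, 1]` (a numeric vector)
#'   or photon rates if `rate_input = TRUE` (photons/ms).
#' @param params A [photoreceptor_params()].
#' @param dt_ms Sampling interval (ms).
#' @param seed Integer seed, or NULL to continue from the current RNG state.
#' @param rate_input Interpret `light` directly as photon rates.
#' @return A `voltage_response` (stage `"photoreceptor"`), with attributes
#'   `raw` (unsaturated bump sum), `n_delivered`, `n_absorbed`,
#'   `n_refractory_lost`.
#' @export
bump_response <- function(light, params = photoreceptor_params(), dt_ms = 1,
                          seed = NULL, rate_input = FALSE) {
  if (any(light < 0)) stop_domain("Light/rate values must be nonnegative.")
  if (!is.null(seed)) set.seed(seed)
  rate <- if (rate_input) light else light * params$photons_per_ms
  rate <- rate + params$dark_noise_rate / 1000
  n <- length(rate)
  tt <- (seq_len(n) - 1) * dt_ms
  free_at <- rep(-Inf, params$n_microvilli)
  bins <- numeric(n)
  delivered <- 0L
  absorbed <- 0L
  for (k in seq_len(n)) {
    nph <- stats::rpois(1, rate[k] * dt_ms)
    if (nph == 0) next
    delivered <- delivered + nph
    ids <- sample.int(params$n_microvilli, nph, replace = TRUE)
    ok <- !duplicated(ids) & (free_at[ids] <= tt[k])
    ids <- ids[ok]
    m <- length(ids)
    if (!m) next
    absorbed <- absorbed + m
    free_at[ids] <- tt[k] + pmax(1, stats::rnorm(m, params$refractory_mean_ms,
                                                 params$refractory_jitter_ms))
    tb <- tt[k] + stats::rnorm(m, 0, params$latency_jitter_ms)
    ib <- pmin(n, pmax(1L, 1L + as.integer(floor(tb / dt_ms))))
    bins <- bins + tabulate(ib, nbins = n)
  }
  kern <- bump_kernel(params, dt_ms)
  raw <- conv_causal(bins, kern)
  new_voltage_response(tt, naka_rushton(raw, params), "photoreceptor",
                       seed = seed, raw = raw, n_delivered = delivered,
                       n_absorbed = absorbed,
                       n_refractory_lost = delivered - absorbed)
}

#' Bump train from explicitly delivered photons
#'
#' Low-level constructor used by [bump_response()]'s machinery and by
#' single-photon checks: places one bump per delivered photon (subject to
#' refractoriness on a single microvillus only if requested) at the given
#' times.
#'
#' @param photon_times_ms Delivery times (ms).
#' @param params A [photoreceptor_params()].
#' @param duration_ms Output duration.
#' @param dt_ms Sampling interval.
#' @param seed Seed for latency jitter.
#' @return A `voltage_response` (stage `"photoreceptor"`).
#' @export
bump_train <- function(photon_times_ms, params = photoreceptor_params(),
                       duration_ms = max(photon_times_ms) + 100, dt_ms = 1,
                       seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- as.integer(ceiling(duration_ms / dt_ms)) + 1L
  tt <- (seq_len(n) - 1) * dt_ms
  tb <- photon_times_ms + stats::rnorm(length(photon_times_ms), 0,
                                       params$latency_jitter_ms)
  ib <- pmin(n, pmax(1L, 1L + as.integer(floor(tb / dt_ms))))
  bins <- tabulate(ib, nbins = n)
  raw <- conv_causal(bins, bump_kernel(params, dt_ms))
  new_voltage_response(tt, naka_rushton(raw, params), "photoreceptor",
                       seed = seed, raw = raw,
                       n_delivered = length(photon_times_ms),
                       n_absorbed = length(photon_times_ms),
                       n_refractory_lost = 0L)
}

#' Deterministic surrogate photoreceptor response
#'
#' Mean-field expectation of the bump model, for fast parameter sweeps: a
#' refractory-depletion ODE gives the expected absorbed-photon rate, which
#' is convolved with the (latency-jitter-smoothed) bump kernel and passed
#' through the same saturating nonlinearity.  On calibration stimuli the
#' surrogate matches the bump model's trial mean within a few percent; a
#' step input produces a transient peak followed by an adapted plateau
#' (microvillus depletion).
#'
#' @inheritParams bump_response
#' @return A `voltage_response` (stage `"photoreceptor"`), deterministic.
#' @export
adaptive_response <- function(light, params = photoreceptor_params(),
                              dt_ms = 1, rate_input = FALSE) {
  if (any(light < 0)) stop_domain("Light/rate values must be nonnegative.")
  rate <- if (rate_input) light else light * params$photons_per_ms
  rate <- rate + params$dark_noise_rate / 1000
  n <- length(rate)
  tt <- (seq_len(n) - 1) * dt_ms
  nv <- params$n_microvilli
  tr <- params$refractory_mean_ms
  f <- numeric(n)
  f[1] <- 1 / (1 + rate[1] * tr / nv)
  if (n > 1) {
    for (k in 2:n) {
      f[k] <- f[k - 1] +
        ((1 - f[k - 1]) / tr - f[k - 1] * rate[k] / nv) * dt_ms
    }
  }
  events <- rate * f * dt_ms  # expected accepted bumps per bin
  if (params$latency_jitter_ms > 0) {
    # smear the expected event train by the (zero-mean) latency jitter so
    # the surrogate matches the jittered bump model's mean
    half <- ceiling(4 * params$latency_jitter_ms / dt_ms)
    g <- stats::dnorm(seq(-half, half) * dt_ms, 0, params$latency_jitter_ms)
    g <- g / sum(g)
    full <- stats::convolve(c(events, numeric(2 * half)), rev(g),
                            type = "open")
    events <- full[half + seq_along(events)]
  }
  raw <- conv_causal(events, bump_kernel(params, dt_ms))
  new_voltage_response(tt, naka_rushton(raw, params), "photoreceptor",
                       raw = raw)
}

#' Sigmoidal intensity dependence of the mass response amplitude
#'
#' Logistic dose--response law in log intensity (Hill form): zero at zero
#' intensity, 0.5 at the midpoint, saturating at 1; monotone throughout.
#'
#' @param intensity Nonnegative intensities.
#' @param i50 Midpoint intensity.
#' @param hill Hill slope.
#' @return Normalised amplitude in `[0, 1]`.
#' @export
erg_amplitude <- function(intensity, i50 = 0.1, hill = 1.5) {
  if (any(intensity < 0)) stop_domain("`intensity` must be nonnegative.")
  x <- (intensity / i50)^hill
  x / (1 + x)
}

#' Phasic large monopolar cell (LMC) transform
#'
#' Sign-inverting band-pass stage modelling the first-order interneuron:
#' a first-order low-pass cascaded with a first-order high-pass, inverted.
#' A constant input decays to zero, and light-on/off steps produce
#' transients of opposite sign.  The pooled variant averages the six
#' neurally superposed photoreceptor inputs before filtering, so six
#' identical inputs give exactly the single-input output.
#'
#' @param v A `voltage_response` of stage `"photoreceptor"`, or a list of
#'   them for the pooled variant.
#' @param tau_hp_ms,tau_lp_ms High- and low-pass time constants (ms).
#' @return A `voltage_response` of stage `"lmc"`.
#' @export
lmc_transform <- function(v, tau_hp_ms = 50, tau_lp_ms = 10) {
  if (is.list(v) && !inherits(v, "voltage_response")) {
    stages <- vapply(v, function(x) attr(x, "stage") %||% "", character(1))
    if (!all(stages == "photoreceptor")) {
      stop_domain("Pooled LMC input must be photoreceptor-stage responses.")
    }
    vv <- rowMeans(vapply(v, function(x) x$v, numeric(nrow(v[[1]]))))
    tt <- v[[1]]$t_ms
  } else {
    if (!identical(attr(v, "stage"), "photoreceptor")) {
      stop_domain("LMC input must be a photoreceptor-stage response.")
    }
    vv <- v$v
    tt <- v$t_ms
  }
  dt <- if (length(tt) > 1) tt[2] - tt[1] else 1
  a_lp <- dt / (tau_lp_ms + dt)
  b_hp <- tau_hp_ms / (tau_hp_ms + dt)
  n <- length(vv)
  lp <- numeric(n)
  lp[1] <- vv[1]
  for (k in seq_len(n - 1) + 1) lp[k] <- lp[k - 1] + a_lp * (vv[k] - lp[k - 1])
  hp <- numeric(n)
  for (k in seq_len(n - 1) + 1) hp[k] <- b_hp * (hp[k - 1] + lp[k] - lp[k - 1])
  new_voltage_response(tt, -hp, "lmc")
}
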