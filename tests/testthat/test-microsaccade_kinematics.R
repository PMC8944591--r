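test_that("saccade amplitude follows Michaelis-Menten kinetics", {
  kp <- kinetics_params()
  expect_equal(saccade_amplitude(0, kp), 0)
  expect_equal(saccade_amplitude(kp$i50, kp), kp$a_max_deg / 2)
  expect_gte(saccade_amplitude(99 * kp$i50, kp), 0.99 * kp$a_max_deg)
  ii <- seq(0, 1, by = 0.05)
  expect_true(all(diff(saccade_amplitude(ii, kp)) >= 0))
  expect_error(saccade_amplitude(-0.1, kp), class = "saccadeye_domain_error")
})

test_that("a saturating flash contracts in 40-50 ms and relaxes within a second", {
  kp <- kinetics_params()
  light <- c(rep(0, 20), rep(1, 10), rep(0, 1500))
  st <- rf_trajectory(light, kp)
  peak_t <- st$t_ms[which.max(st$offset_deg)] - 20
  expect_gte(peak_t, 40)
  expect_lte(peak_t, 50)
  residual <- st$offset_deg[st$t_ms == 20 + 10 + 1000] / max(st$offset_deg)
  expect_lt(residual, 0.05)
  expect_true(all(st$offset_deg >= 0 & st$offset_deg <= kp$a_max_deg))
  expect_true(all(st$narrowing >= 0 & st$narrowing <= kp$narrow_max))
})

test_that("darkness gives zero offset and repeated flashes adapt", {
  kp <- kinetics_params()
  expect_true(all(rf_trajectory(rep(0, 300), kp)$offset_deg == 0))
  l2 <- c(rep(0, 20), rep(1, 10), rep(0, 190), rep(1, 10), rep(0, 300))
  s2 <- rf_trajectory(l2, kp)
  p1 <- max(s2$offset_deg[s2$t_ms < 220])
  p2 <- max(s2$offset_deg[s2$t_ms >= 220])
  expect_lte(p2, p1)
})

test_that("peak offset is monotone in flash intensity", {
  kp <- kinetics_params()
  peaks <- vapply(c(0.02, 0.05, 0.1, 0.3, 0.6, 1), function(i) {
    max(rf_trajectory(c(rep(0, 20), rep(i, 10), rep(0, 300)), kp)$offset_deg)
  }, numeric(1))
  expect_true(all(diff(peaks) >= -1e-12))
})

test_that("the offset is causal with the configured latency", {
  kp <- kinetics_params()
  base <- rep(0.2, 400)
  mod <- base
  mod[201:400] <- 1
  s_base <- rf_trajectory(base, kp)
  s_mod <- rf_trajectory(mod, kp)
  lag <- round(kp$latency_ms)
  expect_identical(s_mod$offset_deg[1:(200 + lag - 1)],
                   s_base$offset_deg[1:(200 + lag - 1)])
  expect_gt(max(abs(s_mod$offset_deg - s_base$offset_deg)), 0)
})

test_that("rf_trajectory rejects bad time bases and intensities", {
  kp <- kinetics_params()
  expect_error(rf_trajectory(rep(0.5, 10), kp, dt_ms = 2),
               class = "saccadeye_domain_error")
  bad <- tibble::tibble(t_ms = c(0, 1, 3, 4), intensity = 0.5)
  expect_error(rf_trajectory(bad, kp), class = "saccadeye_domain_error")
  expect_error(rf_trajectory(c(0.1, -0.1), kp), class = "saccadeye_domain_error")
})

test_that("apply_saccade displaces and narrows while preserving unit integral", {
  kp <- kinetics_params(narrow_max = 0.2)
  st <- rf_trajectory(rep(1, 600), kp)  # steady contracted state
  rf <- receptive_field(0, 0, 5.4, fast_az = 1, fast_el = 0)
  rf0 <- apply_saccade(rf, tibble::tibble(t_ms = c(0, 1), offset_deg = 0,
                                          narrowing = 0, gain = 1), 0.5)
  expect_equal(rf0$center_az_deg, rf$center_az_deg)
  expect_equal(rf0$fwhm_deg, rf$fwhm_deg)

  manual <- tibble::tibble(t_ms = c(0, 1), offset_deg = 2, narrowing = 0.1,
                           gain = 1)
  rf2 <- apply_saccade(rf, manual, 0.5)
  expect_equal(rf2$center_az_deg, 2)
  expect_equal(rf2$fwhm_deg, 5.4 * 0.9)
  # quadrature: the displaced profile integrates to the same mass as the
  # original (displacement by an exact grid multiple, so sums match exactly)
  g <- seq(-30, 30, by = 0.05)
  q0 <- sum(outer(g, g, function(e, a) rf_profile(rf, a, e))) * 0.05^2
  rf_shift <- apply_saccade(rf, tibble::tibble(t_ms = c(0, 1), offset_deg = 2,
                                               narrowing = 0, gain = 1), 0.5)
  q2 <- sum(outer(g, g, function(e, a) rf_profile(rf_shift, a, e))) * 0.05^2
  expect_equal(q0, 1, tolerance = 1e-6)
  expect_lt(abs(q2 - q0), 1e-9)
  expect_error(apply_saccade(rf, manual, 5), class = "saccadeye_domain_error")
})

test_that("mirrored receptive-field pairs displace mirror-symmetrically", {
  kp <- kinetics_params()
  light <- c(rep(0.2, 50), rep(1, 20), rep(0.2, 300))
  st <- rf_trajectory(light, kp)
  rf_l <- receptive_field(-3, 0, 5.4, fast_az = -1, fast_el = 0)
  rf_r <- receptive_field(3, 0, 5.4, fast_az = 1, fast_el = 0)
  a <- apply_saccade(rf_l, st, 100)
  b <- apply_saccade(rf_r, st, 100)
  expect_equal(a$center_az_deg, -b$center_az_deg)
  expect_equal(a$fwhm_deg, b$fwhm_deg)
})
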