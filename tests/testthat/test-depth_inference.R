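test_that("time disparity recovers known lags with sub-sample precision", {
  tt <- 0:599
  pulse <- function(shift) exp(-(tt - 300 - shift)^2 / (2 * 20^2))
  expect_equal(time_disparity(pulse(0), pulse(5), dt_ms = 1), 5,
               tolerance = 1e-3)
  expect_equal(time_disparity(pulse(5), pulse(0), dt_ms = 1), -5,
               tolerance = 1e-3)
  # analytic 4.58 ms offset, 1 ms sampling: parabolic refinement recovers it
  d <- time_disparity(pulse(0), pulse(4.58), dt_ms = 1)
  expect_lt(abs(d - 4.58), 0.1)
  expect_error(time_disparity(rep(1, 100), pulse(0)[1:100], dt_ms = 1),
               class = "saccadeye_flat_error")
})

test_that("velocity estimation inverts the neighbour lag", {
  tt <- 0:599
  pulse <- function(shift) exp(-(tt - 200 - shift)^2 / (2 * 15^2))
  # 4.5 deg in 90 ms -> 50 deg/s
  expect_equal(velocity_estimate(pulse(0), pulse(90), 4.5, dt_ms = 1), 50,
               tolerance = 0.01)
  # doubling the speed halves the lag
  expect_equal(velocity_estimate(pulse(0), pulse(45), 4.5, dt_ms = 1), 100,
               tolerance = 0.02)
  expect_error(velocity_estimate(pulse(0), pulse(0.2), 4.5, dt_ms = 1),
               class = "saccadeye_velocity_error")
  expect_error(velocity_estimate(rep(0, 600), rep(0, 600), 4.5, dt_ms = 1),
               class = "saccadeye_flat_error")
})

test_that("closed-form depth decoding inverts the triangulation", {
  z <- estimate_depth(18.3343, 50, baseline_mm = 0.4)
  expect_equal(z, 25, tolerance = 1e-4)
  expect_error(estimate_depth(0, 50, 0.4), class = "saccadeye_range_error")
  expect_error(estimate_depth(-3, 50, 0.4), class = "saccadeye_range_error")
})

test_that("the calibrated decoder is monotone and recovers its own knots", {
  cal <- default_calibration()
  expect_true(cal$monotone)
  expect_true(cal$direction %in% c("shorter_when_closer", "longer_when_closer"))
  for (i in c(1, 5, 10, nrow(cal$table))) {
    z <- estimate_depth(cal$table$delta_t_ms[i], cal$omega_ref_dps,
                        calibration = cal)
    expect_equal(as.numeric(z), cal$table$z_mm[i], tolerance = 1e-9)
  }
  # the normalised disparity is strictly monotone in depth
  tb <- cal$table[order(cal$table$z_mm), ]
  d <- diff(tb$delta_t_ms)
  expect_true(all(d > 0) || all(d < 0))
})

test_that("simulated transits give the stimulus velocity within 10 percent", {
  cal <- default_calibration()
  expect_true(all(abs(cal$table$omega_hat_dps - 50) / 50 < 0.1))
})

test_that("static-mode disparity matches the trigonometric oracle within 2 percent", {
  ep <- default_eye_pair()
  for (z in c(5, 25, 100, 200)) {
    dd <- deterministic_decode(ep, z, mode = "static", cell = "R7")
    dt <- time_disparity(dd$crop(1), dd$crop(2), dt_ms = 1)
    expected <- disparity_deg(z, ep$config$baseline_mm) / 50 * 1000
    expect_lt(abs(dt - expected) / expected, 0.02)
  }
})

test_that("noiseless closed-loop decoding recovers depth at 25 mm within 1 percent", {
  ep <- default_eye_pair()
  cal <- default_calibration()
  dd <- deterministic_decode(ep, 25)
  res <- saccadeye:::decode_depth(dd$responses[[1]], dd$responses[[2]],
                                  dd$responses[[3]], dd$responses[[4]],
                                  4.5, cal, 0.4)
  expect_lt(abs(res$z_hat_mm - 25) / 25, 0.01)
})

test_that("reversing the stimulus direction flips the disparity sign, not the depth", {
  ep <- default_eye_pair()
  cal <- default_calibration()
  scn <- depth_scenario()
  fwd <- deterministic_decode(ep, 25)
  scene_rev <- mirror_scene(make_dot_pair(
    depth_mm = 25,
    duration_ms = 1000 * (2 * 15 + 3.5) / 50 + 150
  ))
  ro <- saccadeye:::depth_readout(ep, scn)
  # same left/right readout order, reversed stimulus direction
  ids_m <- list(ro$left$pr_id, ro$right$pr_id)
  li <- render_binocular(scene_rev, ep,
                         photoreceptors = dplyr::bind_rows(ro$left, ro$right))
  vs <- lapply(ids_m, function(id) {
    adaptive_response(saccadeye:::light_series(li, id))
  })
  dt_fwd <- time_disparity(fwd$crop(1), fwd$crop(2), dt_ms = 1)
  dt_rev <- time_disparity(saccadeye:::crop_v(vs[[1]], 150),
                           saccadeye:::crop_v(vs[[2]], 150), dt_ms = 1)
  expect_equal(dt_rev, -dt_fwd, tolerance = 1e-9)
  # velocity normalisation makes |z| direction-independent
  z_fwd <- estimate_depth(dt_fwd, 50, calibration = cal)
  z_rev <- estimate_depth(dt_rev, -50, calibration = cal)
  expect_equal(as.numeric(z_rev), as.numeric(z_fwd), tolerance = 1e-9)
})

test_that("depth error curves aggregate trials and failures", {
  ep <- default_eye_pair()
  cal <- default_calibration()
  dec <- depth_error_curve(ep, z_mm = 25, n_trials = 3, calibration = cal,
                           seed = 5)
  expect_identical(nrow(dec$trials), 3L)
  expect_identical(nrow(dec$summary), 1L)
  expect_true(all(!dec$trials$failed))
  expect_true(all(dec$trials$rel_error >= 0))
  td <- tidy(dec)
  expect_identical(td, dec$summary)
  gl <- glance(dec)
  expect_identical(gl$direction, cal$direction)
  expect_error(depth_error_curve(ep, z_mm = -5, n_trials = 3,
                                 calibration = cal),
               class = "saccadeye_domain_error")
  expect_error(depth_error_curve(ep, z_mm = 25, n_trials = 1,
                                 calibration = cal),
               class = "saccadeye_domain_error")
})

test_that("monocular sampling cannot yield a disparity", {
  ep <- default_eye_pair()
  cal <- default_calibration()
  ab <- ablation_experiment(ep, "monocular", n_trials = 3,
                            calibration = cal, seed = 2)
  s <- ab$summary
  expect_equal(s$failure_rate[s$arm == "monocular"], 1)
  expect_equal(s$failure_rate[s$arm == "control"], 0)
  expect_identical(tidy(ab), ab$summary)
  expect_identical(glance(ab)$mode, "monocular")
})
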