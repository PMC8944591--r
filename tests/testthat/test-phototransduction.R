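test_that("darkness without dark noise gives a flat response", {
  p <- photoreceptor_params()
  v <- bump_response(rep(0, 200), p, seed = 1)
  expect_true(all(v$v == 0))
  expect_identical(attr(v, "n_delivered"), 0L)
})

test_that("a single delivered photon produces one bump peaking at time-to-peak", {
  p <- photoreceptor_params(latency_jitter_ms = 0)
  bt <- bump_train(5, p, duration_ms = 80)
  expect_identical(attr(bt, "n_absorbed"), 1L)
  peak_t <- bt$t_ms[which.max(bt$v)]
  expect_lt(abs(peak_t - (5 + p$bump_t_peak_ms)), 2.5)
  expect_true(all(bt$v[bt$t_ms < 5] < 1e-9))  # causal
})

test_that("mean response is linear in photon rate at low rates", {
  p <- photoreceptor_params()
  set.seed(11)
  m1 <- mean(replicate(200, sum(attr(bump_response(rep(0.001, 200), p), "raw"))))
  m2 <- mean(replicate(200, sum(attr(bump_response(rep(0.002, 200), p), "raw"))))
  expect_lt(abs(m2 / m1 - 2), 0.15)
})

test_that("bump bookkeeping is exact and seeded output reproducible", {
  p <- photoreceptor_params()
  v1 <- bump_response(rep(0.5, 300), p, seed = 42)
  v2 <- bump_response(rep(0.5, 300), p, seed = 42)
  expect_identical(v1$v, v2$v)
  expect_identical(attr(v1, "n_delivered") - attr(v1, "n_refractory_lost"),
                   attr(v1, "n_absorbed"))
  expect_gt(attr(v1, "n_refractory_lost"), 0)  # bright light depletes
  # saturation ceiling holds for any drive
  vmax <- bump_response(rep(1, 300), photoreceptor_params(v_max = 0.9),
                        seed = 1)
  expect_true(all(vmax$v <= 0.9))
  expect_error(bump_response(c(-1, 1), p), class = "saccadeye_domain_error")
})

test_that("the deterministic surrogate adapts and matches the bump-model mean", {
  p <- photoreceptor_params()
  step <- c(rep(0, 50), rep(1, 400))
  sur <- adaptive_response(step, p)
  peak <- max(sur$v)
  plateau <- mean(sur$v[400:450])
  expect_gt(peak, plateau)
  expect_identical(sur$v, adaptive_response(step, p)$v)

  flash <- c(rep(0, 50), rep(1, 10), rep(0, 150))
  sf <- adaptive_response(flash, p)
  set.seed(99)
  mc <- rowMeans(vapply(1:100, function(i) bump_response(flash, p)$v,
                        numeric(length(flash))))
  expect_lt(max(abs(mc - sf$v)) / max(sf$v), 0.1)
})

test_that("mass-response amplitude follows a logistic dose-response law", {
  expect_equal(erg_amplitude(0), 0)
  expect_equal(erg_amplitude(0.1, i50 = 0.1), 0.5)
  ii <- 10^seq(-4, 1, by = 0.25)
  a <- erg_amplitude(ii)
  expect_true(all(diff(a) > 0))
  expect_true(all(a >= 0 & a <= 1))
  expect_error(erg_amplitude(-1), class = "saccadeye_domain_error")
})

test_that("the LMC stage is phasic, sign-inverting and pools superposed inputs", {
  p <- photoreceptor_params()
  onoff <- c(rep(0.2, 100), rep(0.8, 200), rep(0.2, 200))
  v <- adaptive_response(onoff, p)
  l <- lmc_transform(v)
  expect_identical(attr(l, "stage"), "lmc")
  # constant input decays to ~0 once the refractory pool settles
  const <- lmc_transform(adaptive_response(rep(0.5, 900), p))
  expect_lt(max(abs(const$v[800:900])), 1e-3)
  # on and off transients have opposite signs (sign-inverted: on is negative)
  on_tr <- l$v[101:140]
  off_tr <- l$v[301:340]
  expect_lt(min(on_tr), 0)
  expect_gt(max(off_tr), 0)
  # pooling six identical inputs equals the single-input output
  pooled <- lmc_transform(list(v, v, v, v, v, v))
  expect_equal(pooled$v, l$v)
  expect_error(lmc_transform(l), class = "saccadeye_domain_error")
  expect_error(lmc_transform(list(l, l, l, l, l, l)),
               class = "saccadeye_domain_error")
})
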