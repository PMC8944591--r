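test_that("eye pair is mirror-symmetric with equatorial offset symmetry", {
  ep <- strip_eye_pair()
  omm <- ep$ommatidia
  l <- omm[omm$eye == "left", ]
  r <- omm[omm$eye == "right", ]
  # every left ommatidium has a right partner at (-az, el) with mirrored
  # fast-phase axis
  key_l <- paste(round(-l$azimuth_deg, 9), round(l$elevation_deg, 9))
  key_r <- paste(round(r$azimuth_deg, 9), round(r$elevation_deg, 9))
  expect_setequal(key_l, key_r)
  m <- merge(l, r, by = "omm_id", suffixes = c(".l", ".r"))
  expect_equal(m$azimuth_deg.l, -m$azimuth_deg.r)
  expect_equal(m$fast_az.l, -m$fast_az.r)
  expect_equal(m$fast_el.l, m$fast_el.r)

  # dorsal and ventral halves mirror the sub-RF elevation offsets
  pr <- merge(ep$photoreceptors[ep$photoreceptors$eye == "right", ],
              r[, c("omm_id", "azimuth_deg", "elevation_deg")],
              by = "omm_id")
  up <- pr[pr$elevation_deg > 1 & pr$cell == "R1", ]
  dn <- pr[pr$elevation_deg < -1 & pr$cell == "R1", ]
  expect_true(all((up$rf_el_deg - up$elevation_deg) > 0))
  expect_true(all((dn$rf_el_deg - dn$elevation_deg) < 0))
})

test_that("lattice neighbours are symmetric and spaced near the interommatidial angle", {
  ep <- strip_eye_pair()
  nb <- ep$neighbors
  expect_true(all(paste(nb$neighbor_id, nb$omm_id) %in%
                    paste(nb$omm_id, nb$neighbor_id)))
  rr <- ep$ommatidia[ep$ommatidia$eye == "right", ]
  m <- merge(nb, rr, by = "omm_id")
  m <- merge(m, rr, by.x = "neighbor_id", by.y = "omm_id",
             suffixes = c("", ".n"))
  frontal <- abs(m$azimuth_deg) <= 15 & abs(m$elevation_deg) <= 15
  d <- saccadeye:::ang_dist_deg(m$azimuth_deg[frontal], m$elevation_deg[frontal],
                                m$azimuth_deg.n[frontal], m$elevation_deg.n[frontal])
  expect_true(all(abs(d - 4.5) / 4.5 < 0.10))
})

test_that("R7/R8 share the optical axis while R1-R6 offsets are distinct", {
  ep <- strip_eye_pair()
  pr <- ep$photoreceptors
  one <- pr[pr$eye == "right" & pr$omm_id == pr$omm_id[1], ]
  r7 <- one[one$cell == "R7", ]
  r8 <- one[one$cell == "R8", ]
  expect_equal(r7$rf_az_deg, r8$rf_az_deg)
  expect_equal(r7$rf_el_deg, r8$rf_el_deg)
  r16 <- one[one$cell %in% paste0("R", 1:6), ]
  expect_equal(nrow(unique(round(r16[, c("rf_az_deg", "rf_el_deg")], 6))), 6)
})

test_that("ommatidium count matches the field/spacing and scales as spacing^-2", {
  ep <- default_eye_pair()
  expect_gt(ep$n_per_eye, 840)
  expect_lt(ep$n_per_eye, 920)
  ep9 <- build_eye_pair(eye_config(interommatidial_deg = 9))
  ratio <- ep9$n_per_eye / ep$n_per_eye
  expect_gt(ratio, 0.2)
  expect_lt(ratio, 0.3)
})

test_that("invalid geometry configuration is rejected", {
  expect_error(eye_config(interommatidial_deg = 0), class = "saccadeye_domain_error")
  expect_error(eye_config(field_az_deg = c(10, 10)), class = "saccadeye_domain_error")
})

test_that("corresponding R6 viewing axes converge in front of the head", {
  ep <- default_eye_pair()
  cp <- corresponding_pair(ep, "R6")
  lf <- cp[cp$eye == "left", ]
  rt <- cp[cp$eye == "right", ]
  expect_equal(lf$rf_az_deg, -rt$rf_az_deg)
  # rays x(y) = +/- k/2 + y * tan(az) from each eye's vantage point
  k <- ep$config$baseline_mm
  tl <- tan(saccadeye:::deg2rad(lf$rf_az_deg))
  tr <- tan(saccadeye:::deg2rad(rt$rf_az_deg))
  y_star <- k / (tl - tr)
  expect_gt(y_star, 0)       # intersection in front of the head
  expect_lt(y_star, 50)      # and at a finite near-field distance (mm)
})

test_that("frontal points are covered by at least 16 photoreceptors, lateral by >= 8", {
  ep <- default_eye_pair()
  expect_gte(coverage_count(ep, 0, 0, 25), 16)
  expect_gte(coverage_count(ep, 60, 0, 100), 8)
  expect_identical(coverage_count(ep, 180, 0, 100), 0L)
})

test_that("coverage count is invariant under azimuth sign flip", {
  ep <- default_eye_pair()
  for (az in c(0, 2.3, 5, 8.7)) {
    expect_identical(coverage_count(ep, az, 1.2, 25),
                     coverage_count(ep, -az, 1.2, 25))
  }
})

test_that("binocular pairs overlap and cover the frontal field", {
  ep <- default_eye_pair()
  bp <- binocular_pairs(ep)
  expect_gt(nrow(bp), 0)
  expect_true(all(bp$separation_deg <
                    5.4))  # < sum of half-widths for equal 5.4-deg FWHMs
  expect_true(all(abs(bp$left_az) <= ep$config$binocular_az_deg / 2))
  # every frontal direction (|az| <= 10 deg on the equator) lies inside the
  # RFs of both members of at least one pair
  for (az in seq(-10, 10, by = 2)) {
    dl <- saccadeye:::ang_dist_deg(bp$left_az, bp$left_el, az, 0)
    dr <- saccadeye:::ang_dist_deg(bp$right_az, bp$right_el, az, 0)
    expect_true(any(dl <= 2.7 & dr <= 2.7))
  }
  # projections of coincident-centre pairs to a 25-mm plane differ by the
  # baseline exactly
  co <- bp[bp$separation_deg < 1e-9, ]
  expect_gt(nrow(co), 0)
  xl <- -0.2 + 25 * tan(saccadeye:::deg2rad(co$left_az))
  xr <- +0.2 + 25 * tan(saccadeye:::deg2rad(co$right_az))
  expect_equal(xr - xl, rep(0.4, nrow(co)), tolerance = 1e-12)
})

test_that("zero-width binocular region yields no pairs", {
  ep <- build_eye_pair(eye_config(field_el_deg = c(-10, 10),
                                  binocular_az_deg = 0))
  expect_identical(nrow(binocular_pairs(ep)), 0L)
})

test_that("RF footprints tile virtual planes completely and scale with depth", {
  ep <- default_eye_pair()
  for (z in c(5, 200)) {
    expect_equal(gap_fraction(rf_tiling(ep, z)), 0)
  }
  p1 <- rf_tiling(ep, 5)
  p2 <- rf_tiling(ep, 10)
  expect_equal(p2$radius_mm, 2 * p1$radius_mm, tolerance = 1e-12)
  # a single isolated ommatidium leaves gaps
  one_omm <- ep$photoreceptors$omm_id[
    ep$photoreceptors$eye == "right" &
      abs(ep$photoreceptors$rf_az_deg) < 1 &
      abs(ep$photoreceptors$rf_el_deg) < 1][1]
  iso <- p1[p1$pr_id %in% ep$photoreceptors$pr_id[
    ep$photoreceptors$omm_id == one_omm & ep$photoreceptors$eye == "right"], ]
  attr(iso, "depth_mm") <- 5
  expect_gt(gap_fraction(iso), 0)
  expect_error(rf_tiling(ep, -1), class = "saccadeye_domain_error")
})

test_that("mirror equivariance: negated azimuths equal swapped eyes", {
  ep <- strip_eye_pair()
  pr <- ep$photoreceptors
  l <- pr[pr$eye == "left", c("omm_id", "cell", "rf_az_deg", "rf_el_deg")]
  r <- pr[pr$eye == "right", c("omm_id", "cell", "rf_az_deg", "rf_el_deg")]
  m <- merge(l, r, by = c("omm_id", "cell"), suffixes = c(".l", ".r"))
  expect_identical(m$rf_az_deg.l, -m$rf_az_deg.r)
  expect_identical(m$rf_el_deg.l, m$rf_el_deg.r)
})
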