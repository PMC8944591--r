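test_that("dot-pair scenes have the stated separation, motion and scaling", {
  sc <- make_dot_pair()
  expect_equal(diff(sc$objects$az_deg), -3.5)
  tr <- scene_tracks(sc, 0.4)
  # when the leading dot is frontal the trailing dot is 3.5 deg behind
  # (head-centric angular positions; compare via the far-field midline time)
  t_mid <- 1000 * abs(sc$objects$az_deg[1]) / sc$motion$speed_dps
  d1 <- tr[tr$object == 1 & tr$eye == "left" & tr$t_ms == t_mid, ]
  expect_equal(d1$az_deg, disparity_deg(25, 0.4) / 2, tolerance = 1e-9)

  static <- make_dot_pair(speed_dps = 0)
  trs <- scene_tracks(static, 0.4)
  expect_equal(length(unique(trs$az_deg[trs$object == 1 & trs$eye == "left"])), 1L)

  d25 <- dot_metric_diameter(make_dot_pair(depth_mm = 25))
  d50 <- dot_metric_diameter(make_dot_pair(depth_mm = 50))
  expect_equal(d50, 2 * d25)
})

test_that("rendered binocular disparity matches 2*atan(k/2z) to 1e-9", {
  for (z in c(25, 100)) {
    sc <- make_dot_pair(depth_mm = z)
    tr <- scene_tracks(sc, 0.4)
    t_mid <- 1000 * abs(sc$objects$az_deg[1]) / sc$motion$speed_dps
    a <- tr[tr$object == 1 & tr$eye == "left" & tr$t_ms == t_mid, ]
    b <- tr[tr$object == 1 & tr$eye == "right" & tr$t_ms == t_mid, ]
    expect_equal(a$az_deg - b$az_deg, disparity_deg(z, 0.4), tolerance = 1e-9)
  }
})

test_that("hidden-dot scenes carry full-contrast stripes and an exact control", {
  sc <- make_hidden_dot_scene()
  m <- raster_scene(sc$control, c(-3, 3), c(-1, 1), 0.05)
  expect_equal(max(m) - min(m), 1)
  # dot removed equals the control exactly
  nodot <- sc
  nodot$objects <- nodot$objects[0, ]
  expect_identical(raster_scene(nodot, c(-3, 3), c(-1, 1), 0.05), m)
  # the dot sits on a white stripe at each of the three arena positions
  for (pos in c(-90, 0, 90)) {
    s <- make_hidden_dot_scene(dot_az_deg = pos)
    r <- raster_scene(s, pos + c(-2, 2), c(-1, 1), 0.05)
    az <- attr(r, "az")
    el <- attr(r, "el")
    expect_equal(r[which.min(abs(el)), which.min(abs(az - pos))], 0)
    rc <- raster_scene(s$control, pos + c(-2, 2), c(-1, 1), 0.05)
    expect_equal(rc[which.min(abs(el)), which.min(abs(az - pos))], 1)
  }
})

test_that("uniform scenes render constant intensities and a constant state", {
  ep <- strip_eye_pair()
  prs <- corresponding_pair(ep, "R7")
  dark <- saccadeye:::new_scene(make_grating_scene(10)$objects,
                                background = 0, duration_ms = 120)
  li <- render_binocular(dark, ep, photoreceptors = prs)
  expect_true(all(li$intensity == 0))
  expect_true(all(vapply(li$states, function(s) all(s$offset_deg == 0),
                         logical(1))))
  bright <- saccadeye:::new_scene(dark$objects, background = 0.8,
                                  duration_ms = 120)
  lb <- render_binocular(bright, ep, photoreceptors = prs)
  expect_equal(max(lb$intensity) - min(lb$intensity), 0)
  off <- lb$states[[1]]$offset_deg
  expect_lt(max(off) - min(off), 1e-9)
})

test_that("rendering is mirror-equivariant bit for bit", {
  ep <- strip_eye_pair()
  scn <- depth_scenario()
  sc <- make_dot_pair(start_az_deg = -8, duration_ms = 350)
  ro <- saccadeye:::depth_readout(ep, scn)
  pair <- dplyr::bind_rows(ro$left, ro$right)
  li <- render_binocular(sc, ep, photoreceptors = pair)
  lim <- render_binocular(mirror_scene(sc), ep, photoreceptors = pair)
  l_id <- as.character(ro$left$pr_id)
  r_id <- as.character(ro$right$pr_id)
  expect_identical(li$intensity[, l_id], lim$intensity[, r_id])
  expect_identical(li$intensity[, r_id], lim$intensity[, l_id])
})

test_that("noise-free rendering is deterministic and Poisson noise is seeded", {
  ep <- strip_eye_pair()
  sc <- make_dot_pair(start_az_deg = -6, duration_ms = 250)
  prs <- corresponding_pair(ep, "R6")
  a <- render_binocular(sc, ep, photoreceptors = prs)
  b <- render_binocular(sc, ep, photoreceptors = prs)
  expect_identical(a$intensity, b$intensity)
  n1 <- render_binocular(sc, ep, photoreceptors = prs,
                         noise_photons_per_ms = 100, seed = 7)
  n2 <- render_binocular(sc, ep, photoreceptors = prs,
                         noise_photons_per_ms = 100, seed = 7)
  n3 <- render_binocular(sc, ep, photoreceptors = prs,
                         noise_photons_per_ms = 100, seed = 8)
  expect_identical(n1$intensity, n2$intensity)
  expect_false(identical(n1$intensity, n3$intensity))
})

test_that("monocular rendering zeroes exactly one eye", {
  ep <- strip_eye_pair()
  sc <- make_dot_pair(start_az_deg = -6, duration_ms = 250)
  prs <- corresponding_pair(ep, "R6")
  li <- render_binocular(sc, ep, photoreceptors = prs, mode = "monocular",
                         side = "left")
  eyes <- li$photoreceptors$eye
  expect_true(all(li$intensity[, eyes == "right"] == 0))
  expect_gt(min(li$intensity[, eyes == "left"]), 0)
  expect_error(render_binocular(sc, ep, photoreceptors = prs,
                                mode = "monocular", side = "both"),
               class = "saccadeye_domain_error")
})

test_that("scene validation rejects bad luminances and time bases", {
  expect_error(make_grating_scene(2, contrast = 1.5),
               class = "saccadeye_domain_error")
  expect_error(make_dot_pair(separation_deg = -1),
               class = "saccadeye_domain_error")
  expect_error(make_dot_pair(dt_ms = 2), class = "saccadeye_domain_error")
})
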