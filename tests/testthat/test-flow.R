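test_that("optic flow matches the closed-form tangential projection", {
  grid <- expand.grid(azimuth_deg = seq(-150, 150, 30),
                      elevation_deg = seq(-60, 60, 30))
  fl <- optic_flow_field(translation = c(0, 1, 0), grid = grid)
  # analytic components for forward translation in the (e_az, e_el) basis
  az <- saccadeye:::deg2rad(grid$azimuth_deg)
  el <- saccadeye:::deg2rad(grid$elevation_deg)
  vx_ref <- sin(az)
  vy_ref <- cos(az) * sin(el)
  expect_equal(fl$vx * fl$magnitude, vx_ref, tolerance = 1e-12)
  expect_equal(fl$vy * fl$magnitude, vy_ref, tolerance = 1e-12)
  # magnitude is sin(angle between r and t)
  cang <- cos(az) * cos(el)
  expect_equal(fl$magnitude, sqrt(1 - cang^2), tolerance = 1e-12)
})

test_that("flow poles, lateral maxima and yaw handedness behave", {
  g <- tibble::tibble(azimuth_deg = c(0, 90, -90), elevation_deg = 0)
  fl <- optic_flow_field(c(0, 1, 0), grid = g)
  expect_equal(fl$magnitude[1], 0)
  expect_equal(fl$magnitude[2:3], c(1, 1))
  expect_equal(fl$vx[2], 1)   # front-to-back on the right side
  expect_equal(fl$vx[3], -1)  # front-to-back on the left side

  yaw <- optic_flow_field(c(0, 0, 0), c(0, 0, 1),
                          grid = tibble::tibble(azimuth_deg = seq(-90, 90, 30),
                                                elevation_deg = 0))
  expect_true(all(abs(yaw$vy) < 1e-12))
  expect_true(all(yaw$vx == yaw$vx[1]))

  z <- optic_flow_field(c(0, 0, 0), c(0, 0, 0), grid = g)
  expect_true(attr(z, "zero_motion"))
  expect_true(all(z$magnitude == 0))
})

test_that("the model direction map is mirror-symmetric and flow-aligned", {
  ep <- strip_eye_pair()
  mp <- microsaccade_direction_map(ep)
  l <- mp[mp$eye == "left", ]
  r <- mp[mp$eye == "right", ]
  l_flip <- l
  l_flip$azimuth_deg <- -l_flip$azimuth_deg
  l_flip$vx <- -l_flip$vx
  key <- function(x) {
    x <- x[order(x$azimuth_deg, x$elevation_deg), ]
    unname(as.matrix(x[, c("azimuth_deg", "elevation_deg", "vx", "vy")]))
  }
  expect_equal(key(l_flip), key(r))

  fm <- flow_match_error(mp, saccadeye:::flow_on_map_grid(mp))
  expect_lt(fm$stats$median_deg, 30)
  # the slow phase runs opposite to the fast phase
  slow <- microsaccade_direction_map(ep, phase = "slow")
  fs <- flow_match_error(mp, slow)
  expect_equal(fs$errors$error_deg, rep(180, nrow(fs$errors)))
})

test_that("flow match error is 0/90/180 degrees for identical, orthogonal and opposed fields", {
  g <- tidyr::crossing(azimuth_deg = seq(-40, 40, 20),
                       elevation_deg = seq(-20, 20, 20))
  a <- dplyr::mutate(g, vx = 1, vy = 0, magnitude = 1)
  expect_equal(flow_match_error(a, a)$errors$error_deg, rep(0, nrow(a)))
  b <- dplyr::mutate(a, vx = 0, vy = 1)
  expect_equal(flow_match_error(a, b)$errors$error_deg, rep(90, nrow(a)))
  d <- dplyr::mutate(a, vx = -1)
  expect_equal(flow_match_error(a, d)$errors$error_deg, rep(180, nrow(a)))
  expect_error(flow_match_error(a, a[-1, ]), class = "saccadeye_domain_error")
})

test_that("vector maps round-trip through CSV, normalising non-unit rows", {
  f <- withr::local_tempfile(fileext = ".csv")
  tb <- tibble::tibble(azimuth_deg = c(0, 10), elevation_deg = c(0, 5),
                       vx = c(2, 0), vy = c(0, 0.5), eye = "left")
  readr::write_csv(tb, f)
  expect_message(mp <- read_vector_map(f), "Normalised")
  expect_equal(sqrt(mp$vx^2 + mp$vy^2), c(1, 1))
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_vector_map(mp, f2)
  mp2 <- read_vector_map(f2)
  expect_equal(mp2$vx, mp$vx)

  bad <- tibble::tibble(azimuth_deg = c(0, NA), elevation_deg = 0,
                        vx = 1, vy = 0)
  readr::write_csv(bad, f)
  expect_error(read_vector_map(f), "row 2", class = "saccadeye_parse_error")
})
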