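#' Eye-pair geometry configuration
#'
#' Parameters of the mirror-symmetric binocular sampling matrix.  The default
#' values describe a fly-like compound eye pair: 4.5 degree interommatidial
#' angle, receptive fields (RFs) of 5.4 degree full width at half maximum
#' (FWHM), R1--R6 sub-RF centres on a 1.5 degree hexagon around the
#' ommatidial axis with R7/R8 on the axis, a 0.4 mm inter-eye baseline
#' between corresponding frontal photoreceptors, and a binocular overlap
#' of about 23.5 degrees of azimuth spanning nearly the full elevation
#' range.  The default per-eye field extent yields roughly 880 ommatidia.
#'
#' @param interommatidial_deg Angular spacing between neighbouring
#'   ommatidial axes (degrees).
#' @param rf_fwhm_deg Photoreceptor RF FWHM (degrees); a scalar or a
#'   length-8 vector for R1--R8.
#' @param subrf_radius_deg Radius of the R1--R6 sub-RF hexagon (degrees).
#' @param baseline_mm Inter-eye separation of corresponding frontal
#'   photoreceptors (mm); the eyes sit at x = +/- baseline_mm / 2.
#' @param field_az_deg Right-eye azimuth extent `c(min, max)` (degrees);
#'   the left eye is its mirror image.
#' @param field_el_deg Elevation extent `c(min, max)` (degrees).
#' @param binocular_az_deg Azimuthal width of the binocular overlap region,
#'   centred on the midline (degrees).
#' @return A list of class `eye_config`.
#' @export
eye_config <- function(interommatidial_deg = 4.5,
                       rf_fwhm_deg = 5.4,
                       subrf_radius_deg = 1.5,
                       baseline_mm = 0.4,
                       field_az_deg = c(-11.75, 123.25),
                       field_el_deg = c(-85, 85),
                       binocular_az_deg = 23.5) {
  assert_scalar_pos(interommatidial_deg, "interommatidial_deg")
  assert_scalar_pos(baseline_mm, "baseline_mm")
  if (!length(rf_fwhm_deg) %in% c(1L, 8L) || any(rf_fwhm_deg <= 0)) {
    stop_domain("`rf_fwhm_deg` must be one or eight positive values.")
  }
  if (diff(field_az_deg) <= 0 || diff(field_el_deg) <= 0) {
    stop_domain("Field extents must be non-empty (`max > min`).")
  }
  if (binocular_az_deg < 0) stop_domain("`binocular_az_deg` must be >= 0.")
  structure(
    list(
      interommatidial_deg = interommatidial_deg,
      rf_fwhm_deg = if (length(rf_fwhm_deg) == 1) rep(rf_fwhm_deg, 8) else rf_fwhm_deg,
      subrf_radius_deg = subrf_radius_deg,
      baseline_mm = baseline_mm,
      field_az_deg = field_az_deg,
      field_el_deg = field_el_deg,
      binocular_az_deg = binocular_az_deg
    ),
    class = "eye_config"
  )
}

# Hexagon angles of the R1-R6 sub-RF centres (degrees, right eye, dorsal
# convention).  R6 sits at 180 degrees, i.e. a pure medial (-azimuth)
# offset in the right eye, so the mirror-symmetric left/right R6 pair has
# converging viewing axes that intersect in front of the head; R7 and R8
# share the ommatidial axis.
subrf_angles <- function() {
  c(R1 = 60, R2 = 120, R3 = 0, R4 = 240, R5 = 300, R6 = 180, R7 = NA, R8 = NA)
}

# Build the right-eye hexagonal lattice on the sphere: elevation rows
# spaced interommatidial * sqrt(3) / 2 apart, azimuth spacing widened by
# 1 / cos(elevation), odd rows offset by half a step.  Row 0 passes
# through (0, 0) so a cartridge looks straight ahead.
right_eye_lattice <- function(config) {
  dphi <- config$interommatidial_deg
  d_el <- dphi * sqrt(3) / 2
  rows <- seq(floor(config$field_el_deg[1] / d_el),
              ceiling(config$field_el_deg[2] / d_el))
  purrr::map_dfr(rows, function(i) {
    el <- i * d_el
    if (el < config$field_el_deg[1] || el > config$field_el_deg[2]) {
      return(NULL)
    }
    step <- dphi / max(cos(deg2rad(el)), 1e-6)
    off <- (abs(i) %% 2) * step / 2
    m <- seq(ceiling((config$field_az_deg[1] - off) / step),
             floor((config$field_az_deg[2] - off) / step))
    if (!length(m)) return(NULL)
    tibble::tibble(row = i, azimuth_deg = off + m * step, elevation_deg = el)
  })
}

# Unit fast-phase RF direction: the local forward-translation optic-flow
# direction, with the azimuthal component constrained to sweep toward the
# eye's own lateral side (the movement axes are anatomically fixed and
# mirror-symmetric between the eyes, so an eye's ommatidia in the narrow
# contralateral overlap strip keep the eye's own sweep direction rather
# than reversing at the frontal flow pole).  At the pole itself the fast
# phase is purely lateral.
fast_phase_dir <- function(az_deg, el_deg, eye_sign) {
  r <- sph_to_cart(az_deg, el_deg)
  t_fwd <- c(0, 1, 0)
  v <- sweep(r * as.numeric(r %*% t_fwd), 2, t_fwd)  # (t.r) r - t
  tb <- tangent_basis(az_deg, el_deg)
  vx <- rowSums(v * tb$e_az)
  vy <- rowSums(v * tb$e_el)
  mag <- sqrt(vx^2 + vy^2)
  degen <- mag < 1e-9
  vx <- ifelse(degen, eye_sign, eye_sign * abs(vx) / pmax(mag, 1e-12))
  vy <- ifelse(degen, 0, vy / pmax(mag, 1e-12))
  tibble::tibble(fast_az = vx, fast_el = vy)
}

# Symmetric lattice neighbour relation: mutual membership among the six
# nearest axes within 1.35 interommatidial angles.
lattice_neighbors <- function(omm, dphi) {
  n <- nrow(omm)
  d <- outer(seq_len(n), seq_len(n), function(i, j) {
    ang_dist_deg(omm$azimuth_deg[i], omm$elevation_deg[i],
                 omm$azimuth_deg[j], omm$elevation_deg[j])
  })
  diag(d) <- Inf
  nb <- lapply(seq_len(n), function(i) {
    cand <- which(d[i, ] <= 1.35 * dphi)
    cand[order(d[i, cand])][seq_len(min(6, length(cand)))]
  })
  pairs <- purrr::map_dfr(seq_len(n), function(i) {
    js <- nb[[i]][vapply(nb[[i]], function(j) i %in% nb[[j]], logical(1))]
    if (!length(js)) return(NULL)
    tibble::tibble(omm_id = omm$omm_id[i], neighbor_id = omm$omm_id[js])
  })
  pairs
}

# Expand one eye's ommatidia into its photoreceptor table under neural
# superposition: R7/R8 view the resident cartridge; each R1-R6 views the
# neighbouring cartridge that lies along its rhabdomere's hexagon bearing
# (or the ideal lattice direction at the eye margin).
eye_photoreceptors <- function(omm, neighbors, config) {
  dphi <- config$interommatidial_deg
  rsub <- config$subrf_radius_deg
  ang <- subrf_angles()
  fwhm <- stats::setNames(config$rf_fwhm_deg, names(ang))

  base <- dplyr::transmute(
    omm,
    omm_id = .data$omm_id,
    axis_az = .data$azimuth_deg,
    axis_el = .data$elevation_deg,
    vmirror = ifelse(.data$elevation_deg < 0, -1, 1)
  )

  # Local bearing (deg; 0 = +azimuth, 90 = +elevation) of each neighbour.
  bear <- dplyr::left_join(neighbors, base, by = "omm_id")
  nb_axis <- dplyr::select(base, neighbor_id = "omm_id",
                           nbr_az = "axis_az", nbr_el = "axis_el")
  bear <- dplyr::left_join(bear, nb_axis, by = "neighbor_id")
  bear$bear_deg <- rad2deg(atan2(
    bear$nbr_el - bear$axis_el,
    (bear$nbr_az - bear$axis_az) * cos(deg2rad(bear$axis_el))
  ))

  r16 <- names(ang)[1:6]
  cand <- tidyr::crossing(cell = r16, bear)
  cand$theta <- unname(ang[cand$cell]) * cand$vmirror
  cand$misalign <- abs(((cand$bear_deg - cand$theta + 180) %% 360) - 180)
  best <- dplyr::slice_min(
    dplyr::group_by(cand, .data$omm_id, .data$cell),
    .data$misalign, n = 1, with_ties = FALSE
  )
  best <- dplyr::ungroup(best)
  best$cartridge_id <- ifelse(best$misalign <= 40, best$neighbor_id, NA_integer_)

  # Ommatidia with no usable neighbour along a bearing (lattice edge) view
  # the ideal lattice direction instead.
  all16 <- tidyr::crossing(cell = r16, base)
  all16 <- dplyr::left_join(
    all16,
    dplyr::select(best, "omm_id", "cell", "cartridge_id", "nbr_az", "nbr_el"),
    by = c("omm_id", "cell")
  )
  all16$theta <- unname(ang[all16$cell]) * all16$vmirror
  miss <- is.na(all16$cartridge_id)
  all16$c_az <- ifelse(
    miss,
    all16$axis_az + dphi * cos(deg2rad(all16$theta)) / cos(deg2rad(all16$axis_el)),
    all16$nbr_az
  )
  all16$c_el <- ifelse(
    miss,
    all16$axis_el + dphi * sin(deg2rad(all16$theta)),
    all16$nbr_el
  )
  pr16 <- dplyr::transmute(
    all16,
    omm_id = .data$omm_id, cell = .data$cell,
    cartridge_id = as.integer(.data$cartridge_id),
    rf_az_deg = .data$c_az +
      rsub * cos(deg2rad(.data$theta)) / cos(deg2rad(.data$c_el)),
    rf_el_deg = .data$c_el + rsub * sin(deg2rad(.data$theta)),
    fwhm_deg = unname(fwhm[.data$cell])
  )

  pr78 <- tidyr::crossing(cell = c("R7", "R8"), base)
  pr78 <- dplyr::transmute(
    pr78,
    omm_id = .data$omm_id, cell = .data$cell,
    cartridge_id = as.integer(.data$omm_id),
    rf_az_deg = .data$axis_az, rf_el_deg = .data$axis_el,
    fwhm_deg = unname(fwhm[.data$cell])
  )
  dplyr::arrange(dplyr::bind_rows(pr16, pr78), .data$omm_id, .data$cell)
}

#' Build a mirror-symmetric binocular eye pair
#'
#' Constructs the left and right compound-eye sampling matrices: hexagonal
#' ommatidial lattices at the configured interommatidial angle, per-ommatidium
#' fast-phase microsaccade axes aligned with the forward-translation optic
#' flow, and the photoreceptor table (R1--R8 per ommatidium) under neural
#' superposition pooling, in which the six R1--R6 of an ommatidium view the
#' six neighbouring cartridges so that every cartridge away from the lattice
#' edge pools signals from seven ommatidia.  The left eye is the exact mirror
#' image (azimuth sign flip) of the right eye, and the dorsal and ventral
#' halves mirror the rhabdomere pattern about the eye equator.
#'
#' @param config An [eye_config()].
#' @return An object of class `eye_pair`: a list with tibbles `ommatidia`
#'   (one row per ommatidium and eye, with fast-phase direction components
#'   `fast_az`, `fast_el`), `neighbors` (symmetric lattice relation within
#'   each eye), and `photoreceptors` (one row per cell, with the viewed RF
#'   centre under superposition), plus the `config` and the binocular region.
#' @examples
#' ep <- build_eye_pair(eye_config(field_el_deg = c(-10, 10)))
#' dplyr::count(ep$ommatidia, eye)
#' @export
build_eye_pair <- function(config = eye_config()) {
  if (!inherits(config, "eye_config")) config <- do.call(eye_config, config)
  right <- right_eye_lattice(config)
  if (!nrow(right)) stop_domain("Eye field is empty; check the configured extents.")
  right$omm_id <- seq_len(nrow(right))
  nbr <- lattice_neighbors(right, config$interommatidial_deg)
  fp <- fast_phase_dir(right$azimuth_deg, right$elevation_deg, eye_sign = 1)
  right <- dplyr::bind_cols(right, fp)
  pr_right <- eye_photoreceptors(right, nbr, config)

  mirror_tbl <- function(tb, az_cols) {
    for (cc in az_cols) tb[[cc]] <- -tb[[cc]]
    tb
  }
  left <- mirror_tbl(right, c("azimuth_deg", "fast_az"))
  pr_left <- mirror_tbl(pr_right, "rf_az_deg")

  omm <- dplyr::bind_rows(
    dplyr::mutate(left, eye = "left"),
    dplyr::mutate(right, eye = "right")
  )
  omm <- dplyr::select(omm, "eye", "omm_id", "azimuth_deg", "elevation_deg",
                       "row", "fast_az", "fast_el")
  pr <- dplyr::bind_rows(
    dplyr::mutate(pr_left, eye = "left"),
    dplyr::mutate(pr_right, eye = "right")
  )
  pr <- dplyr::left_join(
    pr,
    dplyr::select(omm, "eye", "omm_id", "fast_az", "fast_el"),
    by = c("eye", "omm_id")
  )
  pr$pr_id <- seq_len(nrow(pr))
  structure(
    list(
      ommatidia = tibble::as_tibble(omm),
      neighbors = tibble::as_tibble(nbr),
      photoreceptors = tibble::as_tibble(pr),
      config = config,
      binocular_region = list(az_deg = config$binocular_az_deg,
                              el_deg = diff(config$field_el_deg)),
      n_per_eye = nrow(right)
    ),
    class = "eye_pair"
  )
}

#' @export
print.eye_pair <- function(x, ...) {
  cat("<eye_pair>\n")
  cat(sprintf("  %d ommatidia per eye (%.1f deg spacing), %d photoreceptors total\n",
              x$n_per_eye, x$config$interommatidial_deg, nrow(x$photoreceptors)))
  cat(sprintf("  baseline %.2f mm; binocular overlap %.1f deg azimuth\n",
              x$config$baseline_mm, x$config$binocular_az_deg))
  invisible(x)
}

eye_position <- function(eye, baseline_mm) {
  s <- ifelse(eye == "right", 1, -1)
  cbind(s * baseline_mm / 2, 0, 0)
}

# Apparent direction of 3D points (rows of `p`, mm, head frame) from one
# eye's vantage point.
apparent_dir <- function(p, eye, baseline_mm) {
  e <- eye_position(eye, baseline_mm)
  rel <- sweep(matrix(p, ncol = 3), 2, as.numeric(e))
  cart_to_sph(rel)
}

#' Binocularly corresponding photoreceptor pairs
#'
#' Pairs each left-eye photoreceptor whose RF centre lies inside the
#' binocular overlap region with the nearest right-eye photoreceptor centre
#' (ties broken by smaller absolute elevation, then smaller id).  Every
#' returned pair has overlapping receptive fields.
#'
#' @param eye_pair An [build_eye_pair()] result.
#' @return A tibble with one row per pair: ids, RF centres, cell labels and
#'   the angular separation of the two centres.
#' @export
binocular_pairs <- function(eye_pair) {
  half <- eye_pair$config$binocular_az_deg / 2
  if (half <= 0) {
    return(tibble::tibble(left_pr_id = integer(), right_pr_id = integer(),
                          left_az = double(), left_el = double(),
                          right_az = double(), right_el = double(),
                          cell_left = character(), cell_right = character(),
                          separation_deg = double()))
  }
  pr <- eye_pair$photoreceptors
  lf <- dplyr::filter(pr, .data$eye == "left", abs(.data$rf_az_deg) <= half)
  rt <- dplyr::filter(pr, .data$eye == "right", abs(.data$rf_az_deg) <= half)
  if (!nrow(lf) || !nrow(rt)) return(binocular_pairs_empty())
  purrr::map_dfr(seq_len(nrow(lf)), function(i) {
    d <- ang_dist_deg(lf$rf_az_deg[i], lf$rf_el_deg[i],
                      rt$rf_az_deg, rt$rf_el_deg)
    j <- order(d, abs(rt$rf_el_deg), rt$pr_id)[1]
    if (d[j] > (lf$fwhm_deg[i] + rt$fwhm_deg[j]) / 2) return(NULL)
    tibble::tibble(
      left_pr_id = lf$pr_id[i], right_pr_id = rt$pr_id[j],
      left_az = lf$rf_az_deg[i], left_el = lf$rf_el_deg[i],
      right_az = rt$rf_az_deg[j], right_el = rt$rf_el_deg[j],
      cell_left = lf$cell[i], cell_right = rt$cell[j],
      separation_deg = d[j]
    )
  })
}

binocular_pairs_empty <- function() {
  tibble::tibble(left_pr_id = integer(), right_pr_id = integer(),
                 left_az = double(), left_el = double(),
                 right_az = double(), right_el = double(),
                 cell_left = character(), cell_right = character(),
                 separation_deg = double())
}

#' Anatomically corresponding (mirror) photoreceptor pair
#'
#' Returns the left/right photoreceptors of the same cell type in the
#' mirror-symmetric ommatidium pair whose cartridge direction is nearest a
#' requested head-centric direction.  These are the cell pairs whose viewing
#' axes converge in front of the head (e.g. the left and right R6 of the
#' frontal ommatidium pair), the correspondence used by the depth
#' experiments.
#'
#' @param eye_pair An [build_eye_pair()] result.
#' @param cell Photoreceptor label, `"R1"` to `"R8"`.
#' @param azimuth_deg,elevation_deg Requested cartridge direction of the
#'   right-eye member (the left-eye member mirrors it).
#' @return A two-row tibble (left and right member).
#' @export
corresponding_pair <- function(eye_pair, cell = "R6",
                               azimuth_deg = 0, elevation_deg = 0) {
  omm_r <- dplyr::filter(eye_pair$ommatidia, .data$eye == "right")
  d <- ang_dist_deg(azimuth_deg, elevation_deg,
                    omm_r$azimuth_deg, omm_r$elevation_deg)
  oid <- omm_r$omm_id[which.min(d)]
  out <- dplyr::filter(eye_pair$photoreceptors,
                       .data$omm_id == oid, .data$cell == !!cell)
  dplyr::arrange(out, .data$eye)
}

#' Count photoreceptors whose RF contains a point in space
#'
#' Projects the point from each eye's vantage (perspective over the
#' baseline) and counts, across both eyes, the photoreceptors whose RF
#' half-width disk contains the apparent direction.  Each cell is counted
#' once.  Directions outside both eyes' fields simply give zero.
#'
#' @param eye_pair An [build_eye_pair()] result.
#' @param azimuth_deg,elevation_deg Head-centric direction of the point.
#' @param depth_mm Distance of the point from the head centre (mm).
#' @return Integer count.
#' @export
coverage_count <- function(eye_pair, azimuth_deg = 0, elevation_deg = 0,
                           depth_mm = 25) {
  assert_scalar_pos(depth_mm, "depth_mm")
  p <- depth_mm * sph_to_cart(azimuth_deg, elevation_deg)
  pr <- eye_pair$photoreceptors
  n <- 0L
  for (e in c("left", "right")) {
    dir <- apparent_dir(p, e, eye_pair$config$baseline_mm)
    sub <- pr[pr$eye == e, ]
    d <- ang_dist_deg(sub$rf_az_deg, sub$rf_el_deg, dir$az_deg, dir$el_deg)
    n <- n + sum(d <= sub$fwhm_deg / 2)
  }
  as.integer(n)
}

#' Project receptive fields onto a virtual plane
#'
#' Projects every frontal-hemisphere photoreceptor RF onto the plane
#' y = `depth_mm` in front of the head, as a disk whose centre is the
#' intersection of the viewing ray (from that eye's vantage point) with the
#' plane and whose radius is the projected RF half-width.  Footprint
#' diameters grow linearly with depth for a fixed angular FWHM.
#'
#' @param eye_pair An [build_eye_pair()] result.
#' @param depth_mm Plane depth (mm), must be positive.
#' @return A tibble of class `rf_projection` (columns `pr_id`, `eye`,
#'   `cell`, `x_mm`, `z_mm`, `radius_mm`) with the depth as attribute.
#' @export
rf_tiling <- function(eye_pair, depth_mm) {
  assert_scalar_pos(depth_mm, "depth_mm")
  pr <- eye_pair$photoreceptors
  dirs <- sph_to_cart(pr$rf_az_deg, pr$rf_el_deg)
  keep <- dirs[, 2] > 0.2  # frontal hemisphere, away from grazing rays
  pr <- pr[keep, ]
  dirs <- dirs[keep, , drop = FALSE]
  ex <- ifelse(pr$eye == "right", 1, -1) * eye_pair$config$baseline_mm / 2
  t_scale <- depth_mm / dirs[, 2]
  out <- tibble::tibble(
    pr_id = pr$pr_id, eye = pr$eye, cell = pr$cell,
    x_mm = ex + t_scale * dirs[, 1],
    z_mm = t_scale * dirs[, 3],
    radius_mm = t_scale * tan(deg2rad(pr$fwhm_deg / 2))
  )
  structure(out, depth_mm = depth_mm, class = c("rf_projection", class(out)))
}

#' Fraction of a frontal window left uncovered by projected RFs
#'
#' Rasterises a square window of the virtual plane and reports the area
#' fraction not covered by any RF footprint disk.  Zero means the RFs tile
#' the window completely.
#'
#' @param projection An [rf_tiling()] result.
#' @param window_deg Half-width of the frontal window, degrees of visual
#'   angle as seen from the head centre.
#' @param n_grid Raster resolution per axis.
#' @return Scalar gap fraction in `[0, 1]`.
#' @export
gap_fraction <- function(projection, window_deg = 10, n_grid = 121) {
  depth <- attr(projection, "depth_mm")
  half <- depth * tan(deg2rad(window_deg))
  gx <- seq(-half, half, length.out = n_grid)
  gz <- seq(-half, half, length.out = n_grid)
  grid <- expand.grid(x = gx, z = gz)
  keep <- abs(projection$x_mm) < half + max(projection$radius_mm) &
    abs(projection$z_mm) < half + max(projection$radius_mm)
  pp <- projection[keep, ]
  if (!nrow(pp)) return(1)
  covered <- rep(FALSE, nrow(grid))
  for (i in seq_len(nrow(pp))) {
    covered <- covered |
      ((grid$x - pp$x_mm[i])^2 + (grid$z - pp$z_mm[i])^2 <= pp$radius_mm[i]^2)
    if (all(covered)) break
  }
  mean(!covered)
}
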