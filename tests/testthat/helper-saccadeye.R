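# Shared, lazily built fixtures.  The default eye pair and the depth
# calibration are deterministic and moderately expensive, so they are
# built once per test run.

.fixtures <- new.env(parent = emptyenv())

default_eye_pair <- function() {
  if (is.null(.fixtures$ep)) .fixtures$ep <- build_eye_pair()
  .fixtures$ep
}

# A narrow equatorial strip: enough lattice for geometry/kinematics tests
# at a fraction of the cost.
strip_eye_pair <- function() {
  if (is.null(.fixtures$strip)) {
    .fixtures$strip <- build_eye_pair(
      eye_config(field_el_deg = c(-20, 20), field_az_deg = c(-11.75, 40))
    )
  }
  .fixtures$strip
}

default_calibration <- function() {
  if (is.null(.fixtures$cal)) {
    .fixtures$cal <- calibrate_depth_model(default_eye_pair())
  }
  .fixtures$cal
}

# Deterministic (noise-free) depth decode at one depth / mode.
deterministic_decode <- function(ep, z, mode = "microsaccadic",
                                 cell = "R6", ...) {
  scn <- depth_scenario(cell = cell, mode = mode)
  dr <- saccadeye:::depth_render(ep, z, scn, kinetics_params(), mode = mode,
                                 ...)
  ids <- c(dr$readout$left$pr_id, dr$readout$right$pr_id,
           dr$readout$neighbor$pr_id, dr$readout$neighbor2$pr_id)
  vs <- lapply(ids, function(id) {
    adaptive_response(saccadeye:::light_series(dr$light, id))
  })
  list(render = dr, responses = vs,
       crop = function(i) saccadeye:::crop_v(vs[[i]], scn$settle_ms))
}
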