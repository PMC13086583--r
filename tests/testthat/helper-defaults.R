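# Shared fixtures built in code: the default experimental parameter set
# (motor torque ~2 pN um, 5 um body, alpha = 1.5, 20 um/s swimmer; R = 10 um
# puck with thermal diffusivity 6e-5 rad^2/s in a 2x2 um channel).

default_bacterium <- function(...) {
  args <- modifyList(list(motor_torque = 2, body_length = 5,
                          dipole_ratio = 1.5, swim_speed = 20), list(...))
  do.call(torque_dipole_spec, args)
}

default_puck <- function(...) {
  args <- modifyList(list(radius = 10, diffusivity = 6e-5), list(...))
  do.call(puck_state, args)
}

LAMBDA_REF <- 0.17   # analytic-layer workhorse value for closed-form tests

# cache expensive BEM solves across expectations within a test run
.solution_cache <- new.env(parent = emptyenv())
cached <- function(key, expr) {
  if (is.null(.solution_cache[[key]]))
    assign(key, force(expr), envir = .solution_cache)
  .solution_cache[[key]]
}

# small open-channel test geometry (panel invariant h <= W/4 respected)
test_geometry <- function(truncation = 12, h = 0.25, ...)
  channel_geometry(1, truncation_factor = truncation, panel_size = h, ...)
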