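# Minimal collision-rectification model for plain discs in a chiral bath.
#
# E. coli swimming above a no-slip floor trace clockwise circles of radius
# R_c ~ 50 um. Collisions of those curved trajectories with a disc perimeter
# are slightly asymmetric, rectifying a fraction ~ l_B / R_c of the tangential
# collision impulse and producing a slow net clockwise rotation even of
# perfectly symmetric discs.

#' Chiral-bath collision parameters
#'
#' Defaults are calibrated once so that the closed-form rate at R = 10 um is
#' about -3e-3 rad/s, the observed magnitude scale for dilute-bath pucks.
#'
#' @param concentration Bacterial concentration rho_B (cells/mL); bookkeeping
#'   only, the encounter statistics enter through `collision_rate_per_perimeter`.
#' @param curvature_radius Trajectory curvature radius R_c (um); `Inf` gives
#'   achiral swimmers and no rectification.
#' @param body_length Bacterium body length l_B (um).
#' @param force Per-collision tangential force scale F (pN).
#' @param collision_rate_per_perimeter Encounter rate per um of disc perimeter
#'   (s^-1 um^-1).
#' @param contact_time Collision contact time tau_c (s).
#' @param rectification Dimensionless O(1) rectification constant c.
#' @param swim_speed Swim speed (um/s), bookkeeping.
#' @param chirality +1 for clockwise-circling swimmers (wild type above
#'   glass), -1 for the mirrored bath.
#' @return Object of class `"bath_params"`.
#' @export
bath_params <- function(concentration = 6e8, curvature_radius = 50,
                        body_length = 3, force = 0.2,
                        collision_rate_per_perimeter = 0.06,
                        contact_time = 0.3, rectification = 1.5,
                        swim_speed = 20, chirality = 1) {
  check_scalar(curvature_radius, "curvature_radius", positive = TRUE,
               finite = FALSE)
  check_scalar(body_length, "body_length", positive = TRUE)
  check_scalar(force, "force", nonneg = TRUE)
  check_scalar(collision_rate_per_perimeter, "collision_rate_per_perimeter",
               nonneg = TRUE)
  check_scalar(contact_time, "contact_time", positive = TRUE)
  check_scalar(rectification, "rectification", nonneg = TRUE)
  if (!chirality %in% c(-1, 1))
    stop("`chirality` must be +1 or -1", call. = FALSE)
  if (is.finite(curvature_radius) && curvature_radius < 5 * body_length)
    stop("model requires R_c >> l_B", call. = FALSE)
  structure(list(concentration = concentration,
                 curvature_radius = curvature_radius,
                 body_length = body_length, force = force,
                 collision_rate_per_perimeter = collision_rate_per_perimeter,
                 contact_time = contact_time, rectification = rectification,
                 swim_speed = swim_speed, chirality = chirality),
            class = "bath_params")
}

#' Rigid-disc rotational mobility scaling model
#'
#' `M(R) = M0 (R / R0)^-3`: the rotational drag of a rigid disc near a wall
#' grows as the cube of its radius. Defaults anchor the reference at
#' R0 = 10 um with mobility from the measured thermal diffusivity
#' 6e-5 rad^2/s.
#'
#' @param reference_radius R0 (um).
#' @param reference_mobility M0 (rad s^-1 (pN um)^-1).
#' @return Object of class `"disc_mobility"`, callable via [disc_mobility_at()].
#' @export
disc_mobility_model <- function(reference_radius = 10,
                                reference_mobility =
                                  mobility_from_diffusivity(6e-5)) {
  check_scalar(reference_radius, "reference_radius", positive = TRUE)
  check_scalar(reference_mobility, "reference_mobility", positive = TRUE)
  structure(list(reference_radius = reference_radius,
                 reference_mobility = reference_mobility, exponent = -3),
            class = "disc_mobility")
}

#' @rdname disc_mobility_model
#' @param model A `"disc_mobility"`.
#' @param radius Disc radius (um).
#' @export
disc_mobility_at <- function(model, radius) {
  stopifnot(inherits(model, "disc_mobility"))
  model$reference_mobility * (radius / model$reference_radius)^model$exponent
}

#' Mean rectified torque on a disc in a chiral bath
#'
#' `Gamma_bar = -chirality * c * F * (l_B / R_c) * (rate_per_perimeter * 2 pi R) * R * tau_c`:
#' perimeter encounters at rate proportional to R, each transferring a
#' tangential impulse `F tau_c` at lever arm R, rectified by the chirality
#' fraction `l_B / R_c`. The mean torque scales as R^2 at fixed bath
#' parameters and vanishes for straight swimmers (R_c -> Inf).
#'
#' @param params A [bath_params()].
#' @param radius Disc radius R (um).
#' @return Mean torque (pN um); negative (clockwise) for `chirality = +1`.
#' @export
#' @examples
#' mean_rectified_torque(bath_params(), 10)
mean_rectified_torque <- function(params, radius) {
  stopifnot(inherits(params, "bath_params"))
  check_scalar(radius, "radius", positive = TRUE)
  rect <- if (is.finite(params$curvature_radius))
    params$body_length / params$curvature_radius else 0
  rate <- params$collision_rate_per_perimeter * 2 * pi * radius
  -params$chirality * params$rectification * params$force * rect *
    rate * radius * params$contact_time
}

#' Closed-form disc rotation rate in a chiral bath
#'
#' `omega(R) = M(R) * Gamma_bar(R)`. With `M ~ R^-3` and `Gamma_bar ~ R^2`
#' this gives the observed `omega ~ 1/R` scaling.
#'
#' @param params A [bath_params()].
#' @param radius Disc radius (um); vectorized.
#' @param mobility A [disc_mobility_model()].
#' @return Rotation rate (rad/s).
#' @export
#' @examples
#' predicted_rate(bath_params(), c(5, 10, 20), disc_mobility_model())
predicted_rate <- function(params, radius, mobility = disc_mobility_model()) {
  vapply(radius, function(R)
    disc_mobility_at(mobility, R) * mean_rectified_torque(params, R), 0)
}

#' Simulate disc angle time series in a chiral bath
#'
#' Stochastic realization of the closed-form model: collision events are
#' Poisson in time with rate `collision_rate_per_perimeter * 2 pi R`; each
#' event delivers an angular impulse `M(R) F R tau_c` with a rectified mean
#' component `-chirality * c * l_B / R_c` of that scale plus a zero-mean
#' unrectified Gaussian component of unit relative magnitude; thermal
#' rotational diffusion `D(R) = kB T M(R)` is superposed. The ensemble mean
#' drift equals [predicted_rate()] and the short-time fluctuations give an
#' enhanced effective diffusivity.
#'
#' @param params A [bath_params()].
#' @param radius Disc radius (um).
#' @param duration Duration (s).
#' @param dt Time step (s); must resolve the collision rate
#'   (`dt * rate <= 5`).
#' @param seed RNG seed (optional but recommended).
#' @param n_traces Number of independent traces.
#' @param mobility A [disc_mobility_model()].
#' @param temperature Temperature (K) for the thermal diffusivity.
#' @return Object of class `"bath_sim"`: list with `t` and angle matrix
#'   `theta` (rows = times, columns = traces), plus parameters.
#' @export
#' @examples
#' sim <- simulate_bath(bath_params(), 10, duration = 60, dt = 0.1, seed = 1)
#' estimate_rate(data.frame(t_s = sim$t, theta_rad = sim$theta[, 1]))
simulate_bath <- function(params, radius, duration, dt = 0.1, seed = NULL,
                          n_traces = 1L, mobility = disc_mobility_model(),
                          temperature = tp_constants$room_temperature_K) {
  stopifnot(inherits(params, "bath_params"))
  check_scalar(duration, "duration", positive = TRUE)
  check_scalar(dt, "dt", positive = TRUE)
  rate <- params$collision_rate_per_perimeter * 2 * pi * radius
  if (dt * rate > 5)
    stop("`dt` too coarse for the collision rate", call. = FALSE)
  M <- disc_mobility_at(mobility, radius)
  D <- tp_constants$kB_pN_um_per_K * temperature * M
  imp_scale <- M * params$force * radius * params$contact_time
  rect <- if (is.finite(params$curvature_radius))
    params$body_length / params$curvature_radius else 0
  imp_mean <- -params$chirality * params$rectification * rect * imp_scale
  nstep <- ceiling(duration / dt)
  with_seed(seed, {
    nev <- matrix(rpois(nstep * n_traces, rate * dt), nstep, n_traces)
    # sum of n per-event impulses: Normal(n * mean, n * sd^2), exact for
    # Gaussian unrectified components
    kick <- matrix(rnorm(nstep * n_traces), nstep, n_traces) *
      sqrt(nev) * imp_scale + nev * imp_mean
    therm <- matrix(rnorm(nstep * n_traces, sd = sqrt(2 * D * dt)),
                    nstep, n_traces)
    theta <- apply(kick + therm, 2, cumsum)
  })
  theta <- rbind(0, matrix(theta, nstep, n_traces))
  structure(list(t = seq(0, by = dt, length.out = nstep + 1), theta = theta,
                 radius = radius, params = params, dt = dt, seed = seed,
                 mobility = M, diffusivity = D,
                 drift = M * mean_rectified_torque(params, radius)),
            class = "bath_sim")
}

#' @export
print.bath_sim <- function(x, ...) {
  cat(sprintf(
    "bath simulation: R = %g um, %d trace(s) x %.0f s (dt = %g s), model drift %.3g rad/s\n",
    x$radius, ncol(x$theta), max(x$t), x$dt, x$drift))
  invisible(x)
}

#' @export
plot.bath_sim <- function(x, ...) {
  matplot(x$t, x$theta, type = "l", lty = 1,
          col = adjustcolor("steelblue", 0.5),
          xlab = "t (s)", ylab = expression(Theta ~ "(rad)"), ...)
  abline(a = 0, b = x$drift, lty = 2)
  invisible(x)
}
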