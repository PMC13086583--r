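#' Torque-dipole description of a swimming bacterium
#'
#' A flagellated swimmer is represented by two equal and opposite axial point
#' torques of magnitude `motor_torque` (the flagellar-motor torque Gamma_M),
#' separated by the dipole length `l_D = alpha * body_length` along the swim
#' axis. The leading (+Gamma_M x) rotlet sits at the cell body, the trailing
#' (-Gamma_M x) one at the flagellar bundle.
#'
#' @param motor_torque Motor torque magnitude Gamma_M (pN um), > 0 for the
#'   wild-type handedness.
#' @param body_length Cell body length l_B (um).
#' @param dipole_ratio alpha = l_D / l_B (dimensionless).
#' @param swim_speed Swim speed U_s (um/s).
#' @param swim_direction +1 (along +x) or -1.
#' @return Object of class `"torque_dipole"` with derived field
#'   `dipole_length`.
#' @export
#' @examples
#' torque_dipole_spec(2, 5, 1.5, 20)
torque_dipole_spec <- function(motor_torque, body_length, dipole_ratio = 1.5,
                               swim_speed = 20, swim_direction = 1) {
  check_scalar(motor_torque, "motor_torque")
  check_scalar(body_length, "body_length", positive = TRUE)
  check_scalar(dipole_ratio, "dipole_ratio", positive = TRUE)
  check_scalar(swim_speed, "swim_speed", positive = TRUE)
  if (!swim_direction %in% c(-1, 1))
    stop("`swim_direction` must be +1 or -1", call. = FALSE)
  structure(list(motor_torque = motor_torque, body_length = body_length,
                 dipole_ratio = dipole_ratio,
                 dipole_length = dipole_ratio * body_length,
                 swim_speed = swim_speed, swim_direction = swim_direction),
            class = "torque_dipole")
}

#' @export
print.torque_dipole <- function(x, ...) {
  cat(sprintf(
    "torque dipole: Gamma_M = %g pN um, l_B = %g um, alpha = %g (l_D = %g um), U_s = %g um/s\n",
    x$motor_torque, x$body_length, x$dipole_ratio, x$dipole_length,
    x$swim_speed))
  invisible(x)
}

#' Puck (microdisc) state
#'
#' Rotational mobility and diffusivity are linked by the Stokes-Einstein
#' relation `D = M kB T`; either may be supplied and the other is derived. If
#' both are supplied they must agree within 1%.
#'
#' @param radius Disc radius R (um).
#' @param mobility Rotational mobility M_Theta (rad s^-1 (pN um)^-1), optional.
#' @param diffusivity Rotational diffusivity D_Theta (rad^2 s^-1), optional.
#' @param temperature Temperature (K), default 298.15.
#' @param orientation Initial orientation Theta (rad).
#' @return Object of class `"puck_state"`.
#' @export
#' @examples
#' puck_state(10, diffusivity = 6e-5)
puck_state <- function(radius, mobility = NULL, diffusivity = NULL,
                       temperature = tp_constants$room_temperature_K,
                       orientation = 0) {
  check_scalar(radius, "radius", positive = TRUE)
  check_scalar(temperature, "temperature", positive = TRUE)
  kBT <- tp_constants$kB_pN_um_per_K * temperature
  if (is.null(mobility) && is.null(diffusivity))
    stop("supply `mobility` or `diffusivity`", call. = FALSE)
  if (is.null(mobility)) mobility <- diffusivity / kBT
  if (is.null(diffusivity)) diffusivity <- mobility * kBT
  check_scalar(mobility, "mobility", positive = TRUE)
  check_scalar(diffusivity, "diffusivity", nonneg = TRUE)
  if (abs(diffusivity - mobility * kBT) > 0.01 * diffusivity)
    stop("mobility and diffusivity violate the Stokes-Einstein relation by > 1%",
         call. = FALSE)
  structure(list(radius = radius, mobility = mobility,
                 diffusivity = diffusivity, temperature = temperature,
                 orientation = orientation),
            class = "puck_state")
}

#' @export
print.puck_state <- function(x, ...) {
  cat(sprintf(
    "puck: R = %g um, M_Theta = %.4g rad/s/(pN um), D_Theta = %.4g rad^2/s (T = %g K)\n",
    x$radius, x$mobility, x$diffusivity, x$temperature))
  invisible(x)
}

#' Chamber layout of a multi-chamber puck
#'
#' @param n_chambers Number of radial chambers (>= 1).
#' @param dead_end_distance Distance d from the puck centre to each dead-end
#'   wall (um).
#' @param cross_section Length-2, chamber width and height (um).
#' @param occupancy Numeric vector of body lengths of currently trapped
#'   bacteria (length <= `n_chambers`).
#' @return Object of class `"chamber_layout"`.
#' @export
chamber_layout <- function(n_chambers = 4, dead_end_distance = 0.5,
                           cross_section = c(2, 2), occupancy = numeric()) {
  stopifnot(n_chambers >= 1, dead_end_distance >= 0, length(cross_section) == 2)
  if (length(occupancy) > n_chambers)
    stop("more occupants than chambers", call. = FALSE)
  if (length(occupancy) && any(occupancy <= 0))
    stop("occupant body lengths must be positive", call. = FALSE)
  structure(list(n_chambers = as.integer(n_chambers),
                 dead_end_distance = dead_end_distance,
                 cross_section = cross_section, occupancy = occupancy),
            class = "chamber_layout")
}

#' Torque transmitted to the puck by a single rotlet
#'
#' Closed-form transmission law `Gamma_1 = -Lambda (x1 - xC)/W * Gamma_M`.
#'
#' @param lambda Transmission constant (dimensionless, > 0).
#' @param x1 Rotlet axial position (um).
#' @param xC Puck centre axial position (um).
#' @param W Channel half-width (um).
#' @param motor_torque Rotlet torque Gamma_M (pN um), signed.
#' @return Torque about +z (pN um).
#' @export
#' @examples
#' single_rotlet_torque(0.17, 1, 0, 1, 1)  # -0.17
single_rotlet_torque <- function(lambda, x1, xC, W, motor_torque) {
  check_scalar(W, "W", positive = TRUE)
  -lambda * (x1 - xC) / W * motor_torque
}

#' Torque transmitted by the full torque dipole
#'
#' `Gamma = -Lambda (l_D / W) Gamma_M`, independent of the dipole's absolute
#' position (while both rotlets are under the puck) and of the swim direction.
#'
#' @param lambda Transmission constant.
#' @param dipole_length l_D (um).
#' @param W Channel half-width (um).
#' @param motor_torque Gamma_M (pN um).
#' @return Torque about +z (pN um); negative (clockwise) for Gamma_M > 0.
#' @export
#' @examples
#' dipole_torque(0.17, 7.5, 1, 1)  # -1.275
dipole_torque <- function(lambda, dipole_length, W, motor_torque) {
  check_scalar(W, "W", positive = TRUE)
  -lambda * dipole_length / W * motor_torque
}

#' Puck angular velocity from a torque
#'
#' `dTheta/dt = M_Theta * Gamma`.
#'
#' @param torque Torque about z (pN um).
#' @param mobility Rotational mobility (rad s^-1 (pN um)^-1).
#' @return Angular velocity (rad/s).
#' @export
angular_rate <- function(torque, mobility) torque * mobility

#' Puck rotation during a single channel crossing
#'
#' Angular displacement of the puck as a function of the bacterium's position
#' `X_B` in the channel (measured from the entrance), for a bacterium crossing
#' at constant speed. While both rotlets are confined the torque is constant
#' and the response is linear with negative slope (clockwise); once the body
#' exits only the trailing flagellar rotlet drives the puck and the response
#' is the quadratic recovery branch; past the point where the trailing rotlet
#' leaves, the torque vanishes and the angle freezes. The two branches join
#' continuously at the switch point.
#'
#' With the observed convention the switch is at `X* = 2R - l_B`, where the
#' minimum of the down-up shape is found experimentally and where the two
#' printed branches are exactly continuous. The naive convention switches at
#' `X* = 2R` (body centre at the exit), with the quadratic branch continued
#' continuously from there.
#'
#' @param bacterium A [torque_dipole_spec()].
#' @param puck A [puck_state()].
#' @param W Channel half-width (um).
#' @param lambda Torque-transmission constant.
#' @param xb Numeric vector of bacterial positions X_B (um), in
#'   `[0, 2R + l_D]`.
#' @param reversal `"observed"` (default) or `"naive"` switch convention.
#' @return Numeric vector of angular displacements Delta Theta (rad).
#' @export
#' @examples
#' b <- torque_dipole_spec(2, 5, 1.5, 20)
#' p <- puck_state(10, diffusivity = 6e-5)
#' xb <- seq(0, 22.5, by = 0.5)
#' dth <- crossing_profile(b, p, W = 1, lambda = 0.17, xb = xb)
crossing_profile <- function(bacterium, puck, W, lambda, xb,
                             reversal = c("observed", "naive")) {
  stopifnot(inherits(bacterium, "torque_dipole"), inherits(puck, "puck_state"))
  reversal <- match.arg(reversal)
  check_scalar(W, "W", positive = TRUE)
  check_scalar(lambda, "lambda", positive = TRUE)
  R <- puck$radius
  lB <- bacterium$body_length
  lD <- bacterium$dipole_length
  if (any(xb < 0) || any(xb > 2 * R + lD))
    stop("X_B out of range [0, 2R + l_D]", call. = FALSE)
  pref <- lambda * (puck$mobility / bacterium$swim_speed) *
    bacterium$motor_torque / W
  lin <- function(x) -pref * lD * x
  quadr <- function(x) pref * (x^2 / 2 + x * (lB - lD - R) +
                                 lB * (lB - 2 * R) / 2)
  xstar <- if (reversal == "observed") 2 * R - lB else 2 * R
  xend <- max(2 * R - lB + lD, xstar)  # trailing rotlet reaches the exit
  off <- if (reversal == "observed") 0 else lin(xstar) - quadr(xstar)
  out <- ifelse(xb <= xstar, lin(xb),
                ifelse(xb <= xend, quadr(xb) + off, quadr(xend) + off))
  out
}

#' Reversal point and dip depth of the down-up crossing profile
#'
#' @inheritParams crossing_profile
#' @return List with `x_star` (um) and `dtheta_max` (rad, depth of the dip,
#'   positive).
#' @export
#' @examples
#' reversal_point(torque_dipole_spec(2, 5, 1.5, 20),
#'                puck_state(10, diffusivity = 6e-5), W = 1, lambda = 0.17)
reversal_point <- function(bacterium, puck, W, lambda,
                           reversal = c("observed", "naive")) {
  reversal <- match.arg(reversal)
  R <- puck$radius
  lB <- bacterium$body_length
  xstar <- if (reversal == "observed") 2 * R - lB else 2 * R
  depth <- abs(crossing_profile(bacterium, puck, W, lambda, min(xstar, 2 * R + bacterium$dipole_length),
                                reversal = reversal))
  list(x_star = xstar, dtheta_max = depth)
}

#' Rotation rate of a multi-chamber puck
#'
#' The transmitted torques of trapped bacteria are additive, so
#' `omega = sum_i M_Theta * kappa * Gamma(l_D^i)`, where `kappa` is the
#' closed-chamber correction on the open-channel dipole torque (see
#' [closed_chamber_correction()]). Every term is clockwise (negative) for
#' wild-type motor handedness, so rates increase in magnitude as chambers
#' fill and collapse onto the total trapped body length.
#'
#' @param layout A [chamber_layout()]; its `occupancy` lists body lengths.
#' @param bacteria Optional list of [torque_dipole_spec()] for the occupants;
#'   if supplied it overrides `layout$occupancy` lengths. All must share
#'   `motor_torque` sign conventions.
#' @param puck A [puck_state()].
#' @param W Channel half-width (um).
#' @param lambda Transmission constant.
#' @param dipole_ratio alpha used to convert body lengths to dipole lengths
#'   when `bacteria` is not supplied.
#' @param motor_torque Gamma_M used with `layout$occupancy` (pN um).
#' @param correction Closed-chamber torque correction factor kappa; default 1
#'   (open-channel torque). Pass [closed_chamber_correction()] output for the
#'   image-corrected value.
#' @return Rotation rate omega (rad/s).
#' @export
chamber_rate <- function(layout, bacteria = NULL, puck, W, lambda,
                         dipole_ratio = 1.5, motor_torque = 2,
                         correction = 1) {
  stopifnot(inherits(layout, "chamber_layout"), inherits(puck, "puck_state"))
  if (!is.null(bacteria)) {
    if (inherits(bacteria, "torque_dipole")) bacteria <- list(bacteria)
    if (length(bacteria) > layout$n_chambers)
      stop("more bacteria than chambers", call. = FALSE)
    ld <- vapply(bacteria, `[[`, 0, "dipole_length")
    gm <- vapply(bacteria, `[[`, 0, "motor_torque")
  } else {
    if (length(layout$occupancy) > layout$n_chambers)
      stop("more bacteria than chambers", call. = FALSE)
    ld <- dipole_ratio * layout$occupancy
    gm <- rep(motor_torque, length(ld))
  }
  if (!length(ld)) return(0)
  sum(puck$mobility * correction * dipole_torque(lambda, ld, W, gm))
}

#' Order-of-magnitude rate from a bacterium pushing a chamber wall
#'
#' `omega = M_Theta * F * d` for a push force F at lever arm d (the distance
#' from the dead-end wall to the puck centre). This contact estimate falls an
#' order of magnitude short of the observed chamber rates, which singles out
#' the hydrodynamic torque-dipole mechanism.
#'
#' @param force Push force F (pN), >= 0.
#' @param lever_arm d (um), >= 0.
#' @param mobility M_Theta (rad s^-1 (pN um)^-1).
#' @return Rate (rad/s).
#' @export
#' @examples
#' M <- mobility_from_diffusivity(6e-5, 298.15)
#' chamber_push_estimate(0.2, 0.5, M)  # ~1.5e-3 rad/s
chamber_push_estimate <- function(force, lever_arm, mobility) {
  check_scalar(force, "force", nonneg = TRUE)
  check_scalar(lever_arm, "lever_arm", nonneg = TRUE)
  mobility * force * lever_arm
}

#' Effective tangential collision force on a disc perimeter
#'
#' `F* = omega / (M_Theta R)` inverts the mobility relation to express a
#' measured rotation rate as an equivalent steady tangential force acting at
#' the rim.
#'
#' @param omega Rotation rate (rad/s).
#' @param mobility M_Theta (rad s^-1 (pN um)^-1), > 0.
#' @param radius Disc radius R (um), > 0.
#' @return Force (pN).
#' @export
#' @examples
#' effective_tangential_force(1e-3, mobility_from_diffusivity(6e-5), 10)
effective_tangential_force <- function(omega, mobility, radius) {
  check_scalar(mobility, "mobility", positive = TRUE)
  check_scalar(radius, "radius", positive = TRUE)
  omega / (mobility * radius)
}
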