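# Synthetic trajectory generators.
#
# These emulate the statistical structure of the experimental observables:
# channel crossings at constant swim speed with the deterministic down-up
# angular profile plus rotational diffusion and measurement noise; passive
# thermal diffusion traces; and chamber-occupancy event series with stepwise
# rotation rates. Time step default 0.1 s matches 10 frames/s acquisition.

#' Generate a noisy single-bacterium channel-crossing trajectory
#'
#' The deterministic angle is the analytic [crossing_profile()] evaluated at
#' `X_B(t) = U_s t`; rotational diffusion is added by Euler-Maruyama
#' integration and i.i.d. Gaussian measurement noise is applied to both the
#' recorded angle and the recorded bacterial position.
#'
#' @param bacterium A [torque_dipole_spec()].
#' @param puck A [puck_state()]; its `diffusivity` sets the thermal noise.
#' @param W Channel half-width (um).
#' @param lambda Torque-transmission constant.
#' @param noise List with elements `D_theta` (rad^2/s; default the puck's
#'   diffusivity), `angle_sd` (rad) and `position_sd` (um) measurement noise.
#' @param dt Time step (s); must resolve the crossing (`dt << 2R/U_s`).
#' @param seed RNG seed.
#' @param reversal Switch convention, see [crossing_profile()].
#' @return A `"crossing_trajectory"` data frame with columns `t_s`, `xb_um`,
#'   `theta_rad`, and metadata attributes (`bacterium`, `puck`, `W`, `lambda`,
#'   `noise`, `seed`).
#' @export
#' @examples
#' b <- torque_dipole_spec(2, 5, 1.5, 20)
#' p <- puck_state(10, diffusivity = 6e-5)
#' tr <- generate_crossing(b, p, W = 1, lambda = 0.17, seed = 1)
#' head(tr)
generate_crossing <- function(bacterium, puck, W, lambda,
                              noise = list(D_theta = NULL, angle_sd = 0.01,
                                           position_sd = 0.2),
                              dt = 0.1, seed = NULL,
                              reversal = c("observed", "naive")) {
  stopifnot(inherits(bacterium, "torque_dipole"), inherits(puck, "puck_state"))
  reversal <- match.arg(reversal)
  check_scalar(dt, "dt", positive = TRUE)
  R <- puck$radius
  xmax <- 2 * R + bacterium$dipole_length
  t_cross <- xmax / bacterium$swim_speed
  if (dt > t_cross / 10)
    stop("`dt` too coarse to resolve the crossing", call. = FALSE)
  D <- if (is.null(noise$D_theta)) puck$diffusivity else noise$D_theta
  a_sd <- if (is.null(noise$angle_sd)) 0 else noise$angle_sd
  p_sd <- if (is.null(noise$position_sd)) 0 else noise$position_sd
  if (any(c(D, a_sd, p_sd) < 0))
    stop("noise parameters must be >= 0", call. = FALSE)
  tt <- seq(0, t_cross, by = dt)
  xb <- bacterium$swim_speed * tt
  xb[xb > xmax] <- xmax
  det <- crossing_profile(bacterium, puck, W, lambda, xb, reversal = reversal)
  n <- length(tt)
  with_seed(seed, {
    wiener <- c(0, cumsum(rnorm(n - 1, sd = sqrt(2 * D * dt))))
    th_meas <- det + wiener + if (a_sd > 0) rnorm(n, sd = a_sd) else 0
    xb_meas <- xb + if (p_sd > 0) rnorm(n, sd = p_sd) else 0
  })
  out <- data.frame(t_s = tt, xb_um = xb_meas, theta_rad = th_meas)
  structure(out, class = c("crossing_trajectory", "data.frame"),
            bacterium = bacterium, puck = puck, W = W, lambda = lambda,
            noise = list(D_theta = D, angle_sd = a_sd, position_sd = p_sd),
            dt = dt, seed = seed, xb_true = xb, theta_det = det)
}

#' @export
plot.crossing_trajectory <- function(x, ...) {
  plot(x$xb_um, x$theta_rad, type = "l", col = "grey40",
       xlab = expression(X[B] ~ "(um)"),
       ylab = expression(Delta * Theta ~ "(rad)"), ...)
  lines(attr(x, "xb_true"), attr(x, "theta_det"), col = "firebrick", lwd = 2)
  invisible(x)
}

#' Generate a passive rotational-diffusion angle series
#'
#' Pure Wiener process with variance `2 D t`: the null model used to estimate
#' the thermal rotational diffusivity of a puck.
#'
#' @param diffusivity D_Theta (rad^2/s), >= 0.
#' @param duration Total time (s).
#' @param dt Time step (s).
#' @param seed RNG seed.
#' @param n_traces Number of independent traces.
#' @return Data frame `t_s` plus one `theta_rad` column per trace (named
#'   `theta_rad`, `theta_rad_2`, ... when `n_traces > 1`), of class
#'   `"angle_series"`.
#' @export
#' @examples
#' generate_passive(6e-5, duration = 10, dt = 0.1, seed = 1)[1:3, ]
generate_passive <- function(diffusivity, duration, dt = 0.1, seed = NULL,
                             n_traces = 1L) {
  check_scalar(diffusivity, "diffusivity", nonneg = TRUE)
  check_scalar(duration, "duration", positive = TRUE)
  check_scalar(dt, "dt", positive = TRUE)
  n <- ceiling(duration / dt)
  with_seed(seed, {
    inc <- matrix(rnorm(n * n_traces, sd = sqrt(2 * diffusivity * dt)),
                  n, n_traces)
  })
  th <- rbind(0, apply(inc, 2, cumsum))
  out <- data.frame(t_s = seq(0, by = dt, length.out = n + 1))
  nm <- if (n_traces == 1) "theta_rad" else
    c("theta_rad", paste0("theta_rad_", 2:n_traces))
  for (j in seq_along(nm)) out[[nm[j]]] <- th[, j]
  structure(out, class = c("angle_series", "data.frame"),
            diffusivity = diffusivity, dt = dt, seed = seed)
}

#' Generate a chamber-occupancy event series and the puck angle it drives
#'
#' Bacteria enter free chambers as a Poisson process; each occupant adds its
#' clockwise torque contribution, so the mean angle is piecewise linear with
#' slope steps at the entry events (plus rotational diffusion). Occupants
#' remain trapped unless a positive `exit_rate` is given.
#'
#' @param layout A [chamber_layout()].
#' @param body_length_sampler Function `n -> n` body lengths (um) for entering
#'   bacteria; default samples uniform 2-6 um.
#' @param entry_rate Chamber entry rate (s^-1), > 0 unless `duration` only
#'   diffusive behaviour is wanted.
#' @param exit_rate Per-occupant exit rate (s^-1), default 0 (trapped).
#' @param duration Duration (s).
#' @param dt Time step (s).
#' @param puck A [puck_state()].
#' @param W,lambda,dipole_ratio,motor_torque,correction Passed to
#'   [chamber_rate()].
#' @param seed RNG seed.
#' @return List with `events` (data frame `t_s`, `chamber`, `event`,
#'   `body_length_um`), `series` (angle data frame `t_s`, `theta_rad`) and
#'   `rates` (per-step rate, rad/s); class `"occupancy_series"`.
#' @export
generate_occupancy_series <- function(layout, body_length_sampler = NULL,
                                      entry_rate = 0.02, exit_rate = 0,
                                      duration = 600, dt = 0.1,
                                      puck = puck_state(10, diffusivity = 6e-5),
                                      W = 1, lambda = 0.17,
                                      dipole_ratio = 1.5, motor_torque = 2,
                                      correction = 1, seed = NULL) {
  stopifnot(inherits(layout, "chamber_layout"))
  if (entry_rate < 0 || exit_rate < 0)
    stop("rates must be >= 0", call. = FALSE)
  if (is.null(body_length_sampler))
    body_length_sampler <- function(n) runif(n, 2, 6)
  nstep <- ceiling(duration / dt)
  with_seed(seed, {
    occ <- rep(NA_real_, layout$n_chambers)   # body length per chamber
    ev_t <- numeric(); ev_ch <- integer(); ev_kind <- character()
    ev_len <- numeric()
    rate_t <- numeric(nstep)
    inc <- rnorm(nstep, sd = sqrt(2 * puck$diffusivity * dt))
    theta <- numeric(nstep + 1)
    for (i in seq_len(nstep)) {
      free <- which(is.na(occ))
      if (length(free) && runif(1) < entry_rate * dt) {
        ch <- free[sample.int(length(free), 1)]
        occ[ch] <- body_length_sampler(1)
        ev_t <- c(ev_t, (i - 1) * dt); ev_ch <- c(ev_ch, ch)
        ev_kind <- c(ev_kind, "enter"); ev_len <- c(ev_len, occ[ch])
      }
      if (exit_rate > 0) {
        full <- which(!is.na(occ))
        for (ch in full) if (runif(1) < exit_rate * dt) {
          ev_t <- c(ev_t, (i - 1) * dt); ev_ch <- c(ev_ch, ch)
          ev_kind <- c(ev_kind, "exit"); ev_len <- c(ev_len, occ[ch])
          occ[ch] <- NA_real_
        }
      }
      lay_i <- layout
      lay_i$occupancy <- occ[!is.na(occ)]
      rate_t[i] <- chamber_rate(lay_i, NULL, puck, W, lambda,
                                dipole_ratio = dipole_ratio,
                                motor_torque = motor_torque,
                                correction = correction)
      theta[i + 1] <- theta[i] + rate_t[i] * dt + inc[i]
    }
  })
  events <- data.frame(t_s = ev_t, chamber = ev_ch, event = ev_kind,
                       body_length_um = ev_len)
  series <- data.frame(t_s = seq(0, by = dt, length.out = nstep + 1),
                       theta_rad = theta)
  class(series) <- c("angle_series", "data.frame")
  structure(list(events = events, series = series, rates = rate_t,
                 layout = layout, seed = seed),
            class = "occupancy_series")
}

#' @export
print.occupancy_series <- function(x, ...) {
  cat(sprintf("occupancy series: %d events over %.0f s; final rate %.3g rad/s\n",
              nrow(x$events), max(x$series$t_s), tail(x$rates, 1)))
  invisible(x)
}
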