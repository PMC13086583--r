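# Trajectory-level estimators: rotation rates by linear fit, D_Theta by MSAD,
# Stokes-Einstein mobility, crossing collapse, reversal detection, and the
# dipole-ratio fit (the model's single fitting parameter).

.get_theta <- function(series) {
  if (is.numeric(series)) stop("series must be a data frame with t_s/theta_rad",
                               call. = FALSE)
  if (!all(c("t_s", "theta_rad") %in% names(series)))
    stop("series must contain columns `t_s` and `theta_rad`", call. = FALSE)
  list(t = series$t_s, th = series$theta_rad)
}

#' Average rotation rate by linear fit
#'
#' Ordinary least-squares slope of the unwrapped angle against time. Invariant
#' to additive angle offsets and to shifts of the time origin.
#'
#' @param series Data frame with columns `t_s` and `theta_rad`.
#' @return Object of class `"rate_estimate"`: `omega` (rad/s), `se`, `window`.
#' @export
#' @examples
#' s <- generate_passive(6e-5, 60, seed = 1)
#' estimate_rate(s)
estimate_rate <- function(series) {
  v <- .get_theta(series)
  if (length(v$t) < 10) stop("need at least 10 samples", call. = FALSE)
  if (var(v$t) == 0) stop("degenerate time axis", call. = FALSE)
  fit <- lm(v$th ~ v$t)
  # suppress the "essentially perfect fit" note: exact lines are valid input
  structure(list(omega = unname(coef(fit)[2]),
                 se = unname(suppressWarnings(sqrt(diag(vcov(fit)))[2])),
                 window = range(v$t), n = length(v$t)),
            class = "rate_estimate")
}

#' @export
print.rate_estimate <- function(x, ...) {
  cat(sprintf("rotation rate omega = %.4g +/- %.2g rad/s (n = %d, window %.4g-%.4g s)\n",
              x$omega, x$se, x$n, x$window[1], x$window[2]))
  invisible(x)
}

#' Mean squared angular displacement
#'
#' `MSAD(tau) = <(Theta(t + tau) - Theta(t))^2>` over overlapping windows.
#' For pure rotational diffusion it is linear with slope `2 D`; for pure
#' drift it is quadratic, `(omega tau)^2`.
#'
#' @param series Data frame with `t_s` and one or more `theta_rad*` columns
#'   (an ensemble is averaged lag-by-lag).
#' @param lags Integer vector of lags (in samples); default ~20 log-spaced
#'   lags up to a quarter of the series.
#' @return Data frame `tau_s`, `msad_rad2`, `n_pairs`.
#' @export
msad <- function(series, lags = NULL) {
  if (!"t_s" %in% names(series)) stop("series must contain `t_s`", call. = FALSE)
  cols <- grep("^theta_rad", names(series), value = TRUE)
  if (!length(cols)) stop("series must contain `theta_rad` columns", call. = FALSE)
  n <- nrow(series)
  dt <- median(diff(series$t_s))
  if (is.null(lags)) {
    lmax <- max(1L, floor(n / 4))
    lags <- sort(unique(pmax(1L, round(exp(seq(0, log(lmax), length.out = 20))))))
  }
  lags <- lags[lags < n]
  if (!length(lags)) stop("series too short for the requested lags", call. = FALSE)
  th <- as.matrix(series[cols])
  out <- vapply(lags, function(L) {
    d <- th[(1 + L):n, , drop = FALSE] - th[1:(n - L), , drop = FALSE]
    c(mean(d^2), length(d))
  }, c(0, 0))
  data.frame(tau_s = lags * dt, msad_rad2 = out[1, ], n_pairs = out[2, ])
}

#' Rotational diffusivity from the mean squared angular displacement
#'
#' Weighted linear fit of MSAD through the origin over the requested lag
#' range; `D = slope / 2`. The weights are the pair counts per lag. A
#' quadratic component (deterministic drift makes MSAD curve upward) is
#' flagged via the `drift_flag` diagnostic when the quadratic term improves
#' the fit substantially.
#'
#' @param series Data frame with `t_s` and `theta_rad*` columns, or the output
#'   of [msad()].
#' @param lag_range Length-2 numeric, lag-time window (s) used for the fit;
#'   default `[dt, duration/4]`.
#' @return Object of class `"diffusivity_estimate"`: `D` (rad^2/s), `se`,
#'   `lag_range`, `drift_flag`.
#' @export
#' @examples
#' s <- generate_passive(6e-5, 600, seed = 1, n_traces = 20)
#' estimate_diffusivity(s)
estimate_diffusivity <- function(series, lag_range = NULL) {
  m <- if (all(c("tau_s", "msad_rad2") %in% names(series))) series
  else msad(series)
  if (!is.null(lag_range)) {
    if (length(lag_range) != 2 || diff(lag_range) <= 0)
      stop("`lag_range` must be an increasing interval", call. = FALSE)
    m <- m[m$tau_s >= lag_range[1] & m$tau_s <= lag_range[2], ]
  }
  if (nrow(m) < 3) stop("series too short for MSAD estimation", call. = FALSE)
  fit <- lm(msad_rad2 ~ tau_s - 1, data = m, weights = m$n_pairs)
  slope <- unname(coef(fit)[1])
  se <- unname(suppressWarnings(sqrt(diag(vcov(fit)))[1]))
  fit2 <- lm(msad_rad2 ~ tau_s + I(tau_s^2) - 1, data = m,
             weights = m$n_pairs)
  quad <- unname(coef(fit2)[2])
  drift_flag <- is.finite(quad) &&
    abs(quad) * max(m$tau_s) > 0.5 * max(abs(slope), 1e-300)
  structure(list(D = max(slope / 2, 0), se = se / 2,
                 lag_range = range(m$tau_s), drift_flag = drift_flag,
                 msad = m),
            class = "diffusivity_estimate")
}

#' @export
print.diffusivity_estimate <- function(x, ...) {
  cat(sprintf("rotational diffusivity D = %.4g +/- %.2g rad^2/s (lags %.3g-%.3g s)%s\n",
              x$D, x$se, x$lag_range[1], x$lag_range[2],
              if (x$drift_flag) "  [non-diffusive: drift detected]" else ""))
  invisible(x)
}

#' Stokes-Einstein rotational mobility
#'
#' `M_Theta = D_Theta / (kB T)` with the Boltzmann constant in package units
#' (pN um / K).
#'
#' @param diffusivity D_Theta (rad^2/s).
#' @param temperature Temperature (K), > 0.
#' @return Mobility (rad s^-1 (pN um)^-1).
#' @export
#' @examples
#' mobility_from_diffusivity(6e-5, 298.15)  # ~1.46e-2
mobility_from_diffusivity <- function(diffusivity,
                                      temperature = tp_constants$room_temperature_K) {
  check_scalar(temperature, "temperature", positive = TRUE)
  diffusivity / (tp_constants$kB_pN_um_per_K * temperature)
}

#' Collapse crossing trajectories onto a common position grid
#'
#' Re-parameterizes each trace by the bacterial position `X_B` (the
#' low-Reynolds-number collapse variable), interpolates the angle onto a
#' common grid, and returns the pointwise mean and standard deviation.
#' Optionally normalizes angles by each trace's body length, which collapses
#' the pre-reversal branch across sizes.
#'
#' @param trajectories List of `"crossing_trajectory"` data frames (or any
#'   data frames with `xb_um` and `theta_rad`).
#' @param grid Numeric vector of `X_B` values (um); default 64 points over the
#'   common covered range.
#' @param scale_by_length Divide each trace's angle by its body length
#'   (requires the `bacterium` attribute).
#' @return Object of class `"collapsed_crossings"`: data frame `xb_um`,
#'   `mean`, `sd`, `n`.
#' @export
collapse_crossings <- function(trajectories, grid = NULL,
                               scale_by_length = FALSE) {
  if (inherits(trajectories, "data.frame")) trajectories <- list(trajectories)
  for (tr in trajectories) {
    if (!all(c("xb_um", "theta_rad") %in% names(tr)))
      stop("each trajectory needs `xb_um` and `theta_rad`", call. = FALSE)
    if (any(diff(tr$xb_um) < 0) && sum(diff(tr$xb_um) < 0) > 0.2 * nrow(tr))
      stop("non-monotone X_B: not a single crossing", call. = FALSE)
  }
  lo <- max(vapply(trajectories, function(tr) min(tr$xb_um), 0))
  hi <- min(vapply(trajectories, function(tr) max(tr$xb_um), 0))
  if (is.null(grid)) grid <- seq(lo, hi, length.out = 64)
  if (min(grid) < lo - 1e-9 || max(grid) > hi + 1e-9)
    stop("a trajectory does not cover the requested grid", call. = FALSE)
  vals <- vapply(trajectories, function(tr) {
    y <- tr$theta_rad
    if (scale_by_length) {
      b <- attr(tr, "bacterium")
      if (is.null(b)) stop("`scale_by_length` needs bacterium metadata",
                           call. = FALSE)
      y <- y / b$body_length
    }
    approx(tr$xb_um, y, xout = grid, ties = mean)$y
  }, numeric(length(grid)))
  vals <- matrix(vals, nrow = length(grid))
  out <- data.frame(xb_um = grid,
                    mean = rowMeans(vals),
                    sd = apply(vals, 1, sd),
                    n = ncol(vals))
  structure(out, class = c("collapsed_crossings", "data.frame"),
            scale_by_length = scale_by_length)
}

#' @export
plot.collapsed_crossings <- function(x, ...) {
  plot(x$xb_um, x$mean, type = "l", lwd = 2,
       xlab = expression(X[B] ~ "(um)"),
       ylab = if (isTRUE(attr(x, "scale_by_length")))
         expression(Delta * Theta / l[B]) else expression(Delta * Theta ~ "(rad)"),
       ...)
  if (any(is.finite(x$sd)) && max(x$sd, na.rm = TRUE) > 0)
    polygon(c(x$xb_um, rev(x$xb_um)),
            c(x$mean - x$sd, rev(x$mean + x$sd)),
            col = adjustcolor("grey60", 0.4), border = NA)
  lines(x$xb_um, x$mean, lwd = 2)
  invisible(x)
}

#' Locate the reversal point of a collapsed down-up curve
#'
#' Smooths the collapsed mean with a Gaussian kernel and locates the interior
#' minimum; the dip depth is the absolute smoothed value there. Ties are
#' broken toward smaller `X_B`. A curve without an interior minimum raises an
#' error with a diagnostic.
#'
#' @param collapsed A `"collapsed_crossings"` (or data frame with `xb_um`,
#'   `mean`).
#' @param bandwidth Gaussian kernel bandwidth in `X_B` (um), default 1.
#' @return List with `x_star` (um) and `dtheta_max` (rad, positive depth).
#' @export
detect_reversal <- function(collapsed, bandwidth = 1) {
  if (!all(c("xb_um", "mean") %in% names(collapsed)))
    stop("`collapsed` needs columns xb_um and mean", call. = FALSE)
  x <- collapsed$xb_um
  y <- collapsed$mean
  if (bandwidth > 0) {
    sm <- vapply(x, function(x0) {
      w <- exp(-0.5 * ((x - x0) / bandwidth)^2)
      sum(w * y) / sum(w)
    }, 0)
  } else sm <- y
  i <- which(sm == min(sm))[1]   # ties -> smaller X_B
  if (i == 1 || i == length(sm))
    stop(sprintf("no interior minimum (minimum at %s end); curve monotone?",
                 if (i == 1) "left" else "right"), call. = FALSE)
  list(x_star = x[i], dtheta_max = abs(sm[i]), smoothed = sm)
}

#' Fit the dipole-length ratio alpha from crossing trajectories
#'
#' The pre-reversal branch of the crossing law is linear in `X_B` with slope
#' `-Lambda * alpha * l_B * Gamma_M * M_Theta / (W * U_s)`; with all other
#' parameters known, alpha is the model's single fitting parameter. The
#' default pools all pre-reversal samples into one weighted least-squares
#' problem with a cluster-robust (per-trace) standard error; `mode =
#' "per_trace"` instead fits each trace and combines the per-trace estimates
#' by inverse variance.
#'
#' @param trajectories List of `"crossing_trajectory"` objects, or data frames
#'   with `xb_um`/`theta_rad` plus the metadata in `known`.
#' @param known Named list of known parameters: `lambda`, `W`, `motor_torque`,
#'   `mobility`, and per-trace `swim_speed` and `body_length` (scalars are
#'   recycled; defaults are read from trajectory metadata when present).
#' @param mode `"pooled"` (default) or `"per_trace"`.
#' @param prereversal_fraction Use samples with
#'   `X_B <= fraction * (2R - l_B)`; default 0.9.
#' @return Object of class `"alpha_fit"` with methods `print`, `summary`,
#'   `coef`, `confint`, `predict`, `residuals`, `plot`.
#' @export
#' @examples
#' b <- torque_dipole_spec(2, 5, 1.5, 20)
#' p <- puck_state(10, diffusivity = 6e-5)
#' trs <- lapply(1:20, function(i)
#'   generate_crossing(b, p, W = 1, lambda = 0.17, seed = i))
#' fit <- fit_alpha(trs)
#' coef(fit)
fit_alpha <- function(trajectories, known = list(),
                      mode = c("pooled", "per_trace"),
                      prereversal_fraction = 0.9) {
  mode <- match.arg(mode)
  if (inherits(trajectories, "data.frame")) trajectories <- list(trajectories)
  ntr <- length(trajectories)
  if (!ntr) stop("no trajectories", call. = FALSE)
  getp <- function(tr, name, meta_fn) {
    if (!is.null(known[[name]])) return(known[[name]])
    m <- meta_fn(tr)
    if (is.null(m)) stop(sprintf("parameter `%s` neither in `known` nor in metadata",
                                 name), call. = FALSE)
    m
  }
  rows <- list()
  slopes <- numeric(0); slope_vars <- numeric(0); ks <- numeric(0)
  for (i in seq_len(ntr)) {
    tr <- trajectories[[i]]
    lam <- getp(tr, "lambda", function(t) attr(t, "lambda"))
    W <- getp(tr, "W", function(t) attr(t, "W"))
    gm <- getp(tr, "motor_torque",
               function(t) attr(t, "bacterium")$motor_torque)
    Mth <- getp(tr, "mobility", function(t) attr(t, "puck")$mobility)
    Us <- getp(tr, "swim_speed", function(t) attr(t, "bacterium")$swim_speed)
    lB <- getp(tr, "body_length", function(t) attr(t, "bacterium")$body_length)
    R <- getp(tr, "radius", function(t) attr(t, "puck")$radius)
    rec <- function(p) if (length(p) > 1) p[[i]] else p
    lam <- rec(lam); W <- rec(W); gm <- rec(gm); Mth <- rec(Mth)
    Us <- rec(Us); lB <- rec(lB); R <- rec(R)
    keep <- tr$xb_um >= 0 & tr$xb_um <= prereversal_fraction * (2 * R - lB)
    if (sum(keep) < 5)
      stop(sprintf("trajectory %d has insufficient pre-reversal data", i),
           call. = FALSE)
    k_i <- -lam * lB * gm * Mth / (W * Us)   # slope per unit alpha
    rows[[i]] <- data.frame(trace = i, x = tr$xb_um[keep],
                            z = k_i * tr$xb_um[keep],
                            theta = tr$theta_rad[keep])
    sfit <- lm(theta ~ x - 1, data = rows[[i]])
    slopes[i] <- unname(coef(sfit)[1])
    slope_vars[i] <- unname(diag(vcov(sfit))[1])
    ks[i] <- k_i
  }
  dat <- do.call(rbind, rows)
  if (mode == "pooled") {
    alpha <- sum(dat$z * dat$theta) / sum(dat$z^2)
    resid <- dat$theta - alpha * dat$z
    # cluster-robust variance (clusters = traces): random-walk noise within a
    # trace is strongly autocorrelated, so per-sample OLS errors are not i.i.d.
    num <- sum(vapply(split(seq_len(nrow(dat)), dat$trace),
                      function(ii) sum(dat$z[ii] * resid[ii])^2, 0))
    se <- sqrt(num) / sum(dat$z^2)
  } else {
    a_i <- slopes / ks
    v_i <- slope_vars / ks^2
    wgt <- 1 / pmax(v_i, 1e-300)
    alpha <- sum(wgt * a_i) / sum(wgt)
    # empirical scatter between traces (robust to within-trace correlation)
    se <- sqrt(sum(wgt^2 * (a_i - alpha)^2) / sum(wgt)^2)
    resid <- dat$theta - alpha * dat$z
  }
  if (alpha <= 0)
    warning("fitted alpha is not positive; check sign conventions")
  structure(list(alpha = alpha, se = se, mode = mode, n_traces = ntr,
                 n_samples = nrow(dat), data = dat,
                 per_trace = data.frame(trace = seq_len(ntr),
                                        slope = slopes,
                                        slope_se = sqrt(slope_vars),
                                        k = ks, alpha_i = slopes / ks),
                 residual_sd = sd(resid)),
            class = "alpha_fit")
}

#' @export
print.alpha_fit <- function(x, ...) {
  cat(sprintf("dipole-ratio fit: alpha = %.3f +/- %.3f (%s, %d traces, %d samples)\n",
              x$alpha, x$se, x$mode, x$n_traces, x$n_samples))
  invisible(x)
}

#' @export
summary.alpha_fit <- function(object, ...) {
  ci <- confint(object)
  cat(sprintf("Dipole-length ratio alpha = l_D / l_B\n"))
  cat(sprintf("  estimate  %.4f\n  std.err   %.4f\n  95%% CI    [%.4f, %.4f]\n",
              object$alpha, object$se, ci[1], ci[2]))
  cat(sprintf("  mode      %s\n  traces    %d\n  samples   %d\n  resid sd  %.4g rad\n",
              object$mode, object$n_traces, object$n_samples,
              object$residual_sd))
  invisible(object)
}

#' @export
coef.alpha_fit <- function(object, ...) c(alpha = object$alpha)

#' @export
vcov.alpha_fit <- function(object, ...) {
  matrix(object$se^2, 1, 1, dimnames = list("alpha", "alpha"))
}

#' @export
confint.alpha_fit <- function(object, parm, level = 0.95, ...) {
  z <- stats::qnorm(1 - (1 - level) / 2)
  out <- c(object$alpha - z * object$se, object$alpha + z * object$se)
  names(out) <- sprintf("%g %%", 100 * c((1 - level) / 2, 1 - (1 - level) / 2))
  out
}

#' @export
residuals.alpha_fit <- function(object, ...) {
  object$data$theta - object$alpha * object$data$z
}

#' @export
predict.alpha_fit <- function(object, newdata = NULL, ...) {
  d <- if (is.null(newdata)) object$data else newdata
  object$alpha * d$z
}

#' @export
plot.alpha_fit <- function(x, ...) {
  plot(x$data$z, x$data$theta, pch = ".", col = "grey50",
       xlab = "model regressor k * X_B", ylab = expression(Delta * Theta ~ "(rad)"),
       ...)
  abline(0, x$alpha, col = "firebrick", lwd = 2)
  invisible(x)
}

#' Zero-intercept fit of rotation rate against total trapped body length
#'
#' The chamber model predicts `omega` proportional to the summed body lengths
#' of the trapped bacteria; this fits the proportionality through the origin
#' by (optionally weighted) least squares.
#'
#' @param rates Data frame with columns `omega` (rad/s) and `total_length`
#'   (um), optionally `weight`.
#' @return List of class `"length_collapse_fit"`: `slope`, `se`, `residuals`,
#'   `r_squared`.
#' @export
#' @examples
#' d <- data.frame(total_length = c(3, 5, 8, 12), omega = -0.002 * c(3, 5, 8, 12))
#' fit_length_collapse(d)$slope
fit_length_collapse <- function(rates) {
  if (!all(c("omega", "total_length") %in% names(rates)))
    stop("`rates` needs columns omega and total_length", call. = FALSE)
  if (nrow(rates) < 3) stop("need at least 3 points", call. = FALSE)
  w <- if ("weight" %in% names(rates)) rates$weight else rep(1, nrow(rates))
  fit <- lm(omega ~ total_length - 1, data = rates, weights = w)
  res <- residuals(fit)
  structure(list(slope = unname(coef(fit)[1]),
                 se = unname(suppressWarnings(sqrt(diag(vcov(fit)))[1])),
                 residuals = res,
                 r_squared = 1 - sum(w * res^2) /
                   sum(w * (rates$omega - mean(rates$omega))^2),
                 n = nrow(rates)),
            class = "length_collapse_fit")
}

#' @export
print.length_collapse_fit <- function(x, ...) {
  cat(sprintf("length collapse: omega = %.4g * total body length (se %.2g, n = %d)\n",
              x$slope, x$se, x$n))
  invisible(x)
}
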