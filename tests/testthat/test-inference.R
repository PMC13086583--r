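# Estimators: rates, MSAD diffusivity, mobility, collapse, reversal, alpha.

test_that("rate estimator is exact on a line and offset/time-shift invariant", {
  t <- seq(0, 100, by = 0.5)
  s <- data.frame(t_s = t, theta_rad = -0.01 * t + 0.3)
  r <- estimate_rate(s)
  expect_equal(r$omega, -0.01, tolerance = 1e-12)
  s2 <- data.frame(t_s = t + 50, theta_rad = -0.01 * t + 1.3)
  expect_equal(estimate_rate(s2)$omega, r$omega, tolerance = 1e-12)
  expect_error(estimate_rate(s[1:5, ]), "at least 10")
  expect_error(estimate_rate(data.frame(t_s = rep(1, 20),
                                        theta_rad = rnorm(20))),
               "degenerate")
})

test_that("rate recovery on synthetic bath drift is within 3 standard errors", {
  sim <- simulate_bath(bath_params(), 10, duration = 600, dt = 0.1, seed = 31,
                       n_traces = 50)
  om <- vapply(seq_len(50), function(j)
    estimate_rate(data.frame(t_s = sim$t, theta_rad = sim$theta[, j]))$omega, 0)
  expect_lt(abs(mean(om) - sim$drift), 3 * sd(om) / sqrt(50))
})

test_that("MSAD matches closed forms: 2 D tau for diffusion, (omega tau)^2 for drift", {
  t <- seq(0, 200, by = 0.1)
  drift <- data.frame(t_s = t, theta_rad = -0.02 * t)
  m <- msad(drift, lags = c(10, 50, 100))
  expect_equal(m$msad_rad2, (0.02 * m$tau_s)^2, tolerance = 1e-10)
  d <- estimate_diffusivity(drift)
  expect_true(d$drift_flag)
  const <- data.frame(t_s = t, theta_rad = rep(1.2, length(t)))
  expect_equal(estimate_diffusivity(const)$D, 0)
  s <- generate_passive(6e-5, 600, seed = 4, n_traces = 80)
  est <- estimate_diffusivity(s)
  expect_equal(est$D, 6e-5, tolerance = 0.15)
  expect_false(est$drift_flag)
  expect_error(estimate_diffusivity(s, lag_range = c(5, 1)), "increasing")
})

test_that("Stokes-Einstein mobility uses the exact Boltzmann constant", {
  expect_identical(mobility_from_diffusivity(0), 0)
  m <- mobility_from_diffusivity(6e-5, 298.15)
  expect_equal(m, 6e-5 / (1.380649e-5 * 298.15), tolerance = 1e-12)
  expect_equal(m, 1.46e-2, tolerance = 0.01)
  expect_equal(mobility_from_diffusivity(1.2e-4, 298.15), 2 * m,
               tolerance = 1e-12)
  # kB in pN um per K is the SI value times 1e7 (1 J = 1e12 pN * 1e6 um... /K)
  expect_equal(tp_constants$kB_pN_um_per_K, 1.380649e-23 * 1e12 * 1e6,
               tolerance = 1e-15)
})

test_that("crossings with different speeds collapse exactly at fixed torque/speed ratio", {
  p <- default_puck()
  mk <- function(us) default_bacterium(swim_speed = us, motor_torque = 0.1 * us)
  # dt ~ 1/U_s keeps the X_B sample points identical across speeds, so the
  # collapse is exact rather than limited by interpolation
  trs <- lapply(c(10, 15, 20, 30), function(us)
    generate_crossing(mk(us), p, 1, LAMBDA_REF, seed = 1, dt = 1 / us,
                      noise = list(D_theta = 0, angle_sd = 0, position_sd = 0)))
  cc <- collapse_crossings(trs)
  expect_true(all(cc$sd < 1e-12))
  expect_equal(cc$n[1], 4)
})

test_that("body-length scaling shrinks the pre-reversal dispersion at least twofold", {
  p <- default_puck()
  trs <- lapply(c(3, 4, 5, 6, 7), function(lb)
    generate_crossing(default_bacterium(body_length = lb), p, 1, LAMBDA_REF,
                      seed = 1,
                      noise = list(D_theta = 0, angle_sd = 0, position_sd = 0)))
  grid <- seq(0.5, 0.85 * (2 * 10 - 7), length.out = 30)  # pre-reversal for all
  raw <- collapse_crossings(trs, grid = grid)
  scl <- collapse_crossings(trs, grid = grid, scale_by_length = TRUE)
  disp <- function(cc) mean(cc$sd / pmax(abs(cc$mean), 1e-12))
  expect_gt(disp(raw) / disp(scl), 2)
})

test_that("reversal detection finds the analytic switch point and orders dips by body length", {
  b <- default_bacterium()
  p <- default_puck()
  xb <- seq(0, 22.5, by = 0.25)
  cc <- data.frame(xb_um = xb,
                   mean = crossing_profile(b, p, 1, LAMBDA_REF, xb))
  rv <- detect_reversal(cc, bandwidth = 0)
  expect_equal(rv$x_star, 15, tolerance = 1e-9)
  expect_equal(rv$dtheta_max,
               reversal_point(b, p, 1, LAMBDA_REF)$dtheta_max,
               tolerance = 1e-9)
  # noisy ensemble: recovered within one grid cell
  trs <- lapply(1:150, function(i)
    generate_crossing(b, p, 1, LAMBDA_REF, seed = 400 + i))
  ccn <- collapse_crossings(trs)
  rvn <- detect_reversal(ccn)
  cell <- diff(ccn$xb_um[1:2])
  expect_lt(abs(rvn$x_star - 15), max(cell, 1))
  # deeper dip for longer bodies
  depth <- vapply(c(4, 6), function(lb) {
    bb <- default_bacterium(body_length = lb)
    xx <- seq(0, 2 * 10 + bb$dipole_length, by = 0.25)
    detect_reversal(data.frame(
      xb_um = xx, mean = crossing_profile(bb, p, 1, LAMBDA_REF, xx)),
      bandwidth = 0)$dtheta_max
  }, 0)
  expect_gt(depth[2], depth[1])
  mono <- data.frame(xb_um = 1:20, mean = -(1:20))
  expect_error(detect_reversal(mono), "minimum")
})

test_that("alpha is recovered exactly from noiseless data and well from noisy ensembles", {
  b <- default_bacterium()   # alpha = 1.5
  p <- default_puck()
  tr0 <- generate_crossing(b, p, 1, LAMBDA_REF, seed = 1,
                           noise = list(D_theta = 0, angle_sd = 0,
                                        position_sd = 0))
  suppressWarnings(f0 <- fit_alpha(list(tr0)))
  expect_equal(unname(coef(f0)), 1.5, tolerance = 1e-10)
  trs <- lapply(1:200, function(i)
    generate_crossing(b, p, 1, LAMBDA_REF, seed = 600 + i))
  f <- fit_alpha(trs)
  expect_lt(abs(f$alpha - 1.5) / 1.5, 0.10)
  ci <- confint(f)
  expect_true(ci[1] <= 1.5 && 1.5 <= ci[2])
  fp <- fit_alpha(trs, mode = "per_trace")
  expect_equal(fp$alpha, f$alpha, tolerance = 0.05)
  # methods behave like a fitted model object
  expect_named(coef(f), "alpha")
  expect_equal(dim(vcov(f)), c(1L, 1L))
  expect_length(residuals(f), f$n_samples)
  expect_equal(predict(f), f$data$theta - residuals(f), tolerance = 1e-12)
  expect_output(print(f), "alpha")
})

test_that("alpha bias over repeated ensembles is below 3%", {
  b <- default_bacterium()
  p <- default_puck()
  ah <- vapply(0:4, function(k) {
    trs <- lapply(1:80, function(i)
      generate_crossing(b, p, 1, LAMBDA_REF, seed = 2000 + 100 * k + i))
    fit_alpha(trs)$alpha
  }, 0)
  expect_lt(abs(mean(ah) / 1.5 - 1), 0.03)
})

test_that("length-collapse fit is exact on proportional data and order invariant", {
  d <- data.frame(total_length = c(3, 5, 8, 12, 16),
                  omega = -2e-3 * c(3, 5, 8, 12, 16))
  f <- fit_length_collapse(d)
  expect_equal(f$slope, -2e-3, tolerance = 1e-12)
  expect_equal(max(abs(f$residuals)), 0, tolerance = 1e-15)
  perm <- d[c(4, 1, 5, 3, 2), ]
  expect_equal(fit_length_collapse(perm)$slope, f$slope, tolerance = 1e-12)
  expect_error(fit_length_collapse(d[1:2, ]), "at least 3")
  # synthetic occupancy rates are consistent with the model line
  p <- default_puck()
  lens <- list(3, c(3, 4), c(3, 4, 5), c(3, 4, 5, 3.5))
  occ <- data.frame(
    total_length = vapply(lens, sum, 0),
    omega = vapply(lens, function(l)
      chamber_rate(chamber_layout(occupancy = l), NULL, p, 1, 0.17), 0))
  fo <- fit_length_collapse(occ)
  pred_slope <- chamber_rate(chamber_layout(occupancy = 1), NULL, p, 1, 0.17)
  expect_equal(fo$slope, pred_slope, tolerance = 1e-10)
})
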