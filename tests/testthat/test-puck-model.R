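# Analytic torques and angular dynamics.

test_that("single-rotlet and dipole transmission laws evaluate exactly", {
  expect_identical(single_rotlet_torque(0.17, 1, 1, 1, 1), 0)
  expect_equal(single_rotlet_torque(0.17, 1, 0, 1, 1), -0.17)
  # odd in the offset
  expect_equal(single_rotlet_torque(0.17, -1, 0, 1, 1),
               -single_rotlet_torque(0.17, 1, 0, 1, 1))
  expect_identical(dipole_torque(0.17, 0, 1, 1), 0)
  expect_equal(dipole_torque(0.17, 7.5, 1, 1), -1.275)
  # linear in every factor
  expect_equal(dipole_torque(0.17, 7.5, 1, 3), 3 * dipole_torque(0.17, 7.5, 1, 1))
  expect_equal(angular_rate(0, 0.01), 0)
  expect_equal(angular_rate(-2, 0.02), -0.04)
})

test_that("linear and quadratic crossing branches are continuous at 2R - lB for random draws", {
  set.seed(42)
  for (i in 1:200) {
    R <- runif(1, 5, 25)
    lB <- runif(1, 1, min(8, R))
    b <- default_bacterium(body_length = lB,
                           dipole_ratio = runif(1, 0.5, 3),
                           motor_torque = runif(1, 0.5, 5),
                           swim_speed = runif(1, 5, 40))
    p <- default_puck(radius = R)
    W <- runif(1, 0.5, 2)
    lam <- runif(1, 0.05, 0.5)
    xs <- 2 * R - lB
    left <- crossing_profile(b, p, W, lam, xs - 1e-9)
    right <- crossing_profile(b, p, W, lam, xs + 1e-9)
    expect_equal(left, right, tolerance = 1e-6)
    # and the closed-form value at the switch point
    expect_equal(crossing_profile(b, p, W, lam, xs),
                 -lam * (b$dipole_length / W) * (p$mobility / b$swim_speed) *
                   b$motor_torque * xs,
                 tolerance = 1e-12)
  }
})

test_that("crossing profile has the down-up shape with its minimum at the switch point", {
  b <- default_bacterium()
  p <- default_puck()
  xb <- seq(0, 2 * p$radius + b$dipole_length, by = 0.05)
  dth <- crossing_profile(b, p, 1, LAMBDA_REF, xb)
  xs <- 2 * p$radius - b$body_length
  expect_equal(dth[1], 0)
  expect_true(all(diff(dth[xb <= xs]) <= 1e-12))        # non-increasing before
  after <- xb > xs & xb <= 2 * p$radius - b$body_length + b$dipole_length
  expect_true(all(diff(dth[after]) >= -1e-12))          # non-decreasing after
  expect_equal(xb[which.min(dth)], xs, tolerance = 0.06)
  # frozen after the trailing rotlet leaves
  tailv <- dth[xb >= 2 * p$radius - b$body_length + b$dipole_length]
  expect_true(all(abs(diff(tailv)) < 1e-15))
  expect_error(crossing_profile(b, p, 1, LAMBDA_REF, -1), "out of range")
})

test_that("profile vs position is speed-invariant at fixed torque-to-speed ratio", {
  p <- default_puck()
  xb <- seq(0, 20, by = 0.5)
  b1 <- default_bacterium(swim_speed = 10, motor_torque = 1)
  b2 <- default_bacterium(swim_speed = 20, motor_torque = 2)
  expect_equal(crossing_profile(b1, p, 1, LAMBDA_REF, xb),
               crossing_profile(b2, p, 1, LAMBDA_REF, xb), tolerance = 1e-12)
})

test_that("reversal point matches the printed geometry and scaling", {
  b <- default_bacterium()   # lB = 5
  p <- default_puck()        # R = 10
  rv <- reversal_point(b, p, 1, LAMBDA_REF)
  expect_equal(rv$x_star, 15)
  expect_equal(rv$dtheta_max,
               LAMBDA_REF * (7.5 / 1) * (p$mobility / 20) * 2 * 15,
               tolerance = 1e-12)
  # larger body: earlier reversal, deeper dip
  b2 <- default_bacterium(body_length = 7)
  rv2 <- reversal_point(b2, p, 1, LAMBDA_REF)
  expect_lt(rv2$x_star, rv$x_star)
  expect_gt(rv2$dtheta_max, rv$dtheta_max)
  # depth scaled by lB is body-length independent to first order in lB/2R
  d1 <- rv$dtheta_max / 5
  d2 <- rv2$dtheta_max / 7
  expect_equal(d1, d2, tolerance = 0.2)
  # the naive convention switches at 2R instead
  expect_equal(reversal_point(b, p, 1, LAMBDA_REF, reversal = "naive")$x_star, 20)
})

test_that("chamber rates are additive, clockwise, and collapse on total length", {
  p <- default_puck()
  empty <- chamber_layout(occupancy = numeric())
  expect_identical(chamber_rate(empty, NULL, p, 1, LAMBDA_REF), 0)
  lens <- c(3, 4.5, 2.5, 5)
  singles <- vapply(lens, function(l)
    chamber_rate(chamber_layout(occupancy = l), NULL, p, 1, LAMBDA_REF), 0)
  expect_true(all(singles < 0))
  cum <- vapply(seq_along(lens), function(k)
    chamber_rate(chamber_layout(occupancy = lens[1:k]), NULL, p, 1, LAMBDA_REF), 0)
  expect_true(all(diff(abs(cum)) > 0))   # strictly faster as chambers fill
  expect_equal(cum[4], sum(singles), tolerance = 1e-14)
  # two bacteria of lengths a and b = one of length a + b under the collapse
  ab <- chamber_rate(chamber_layout(occupancy = c(3, 4)), NULL, p, 1, LAMBDA_REF)
  onebig <- chamber_rate(chamber_layout(occupancy = 7), NULL, p, 1, LAMBDA_REF)
  expect_equal(ab, onebig, tolerance = 1e-14)
  expect_error(chamber_rate(chamber_layout(n_chambers = 2, occupancy = c(1, 2)),
                            list(default_bacterium(), default_bacterium(),
                                 default_bacterium()),
                            p, 1, LAMBDA_REF), "more bacteria")
})

test_that("contact push estimate and effective tangential force match the printed scales", {
  M <- mobility_from_diffusivity(6e-5, 298)
  expect_identical(chamber_push_estimate(0, 0.5, M), 0)
  w <- chamber_push_estimate(0.2, 0.5, M)
  # one-significant-figure published estimate 2e-3 rad/s within a factor 1.5
  expect_lt(max(w / 2e-3, 2e-3 / w), 1.5)
  expect_equal(chamber_push_estimate(0.2, 1, M), 2 * w, tolerance = 1e-12)
  expect_identical(effective_tangential_force(0, M, 10), 0)
  f <- effective_tangential_force(1e-3, M, 10)
  expect_gte(f, 0.006)
  expect_lte(f, 0.06)
  # algebraic round trip: torque F* R back through the mobility gives omega
  expect_equal(angular_rate(f * 10, M), 1e-3, tolerance = 1e-12)
})

test_that("closed-form layer is invariant under a consistent unit rescaling", {
  # (um, s, pN) -> (2 um, 2 s, 2 pN): lengths x2, torques x4, speeds x1,
  # mobilities x1/8, diffusivities x1/2, temperatures (energy kB T) x4.
  s <- 2
  expect_equal(dipole_torque(0.17, 7.5 * s, 1 * s, 1 * s^2),
               s^2 * dipole_torque(0.17, 7.5, 1, 1), tolerance = 1e-12)
  expect_equal(angular_rate(-1.2 * s^2, 0.01 / s^3),
               angular_rate(-1.2, 0.01) / s, tolerance = 1e-12)
  b1 <- default_bacterium()
  p1 <- default_puck()
  b2 <- torque_dipole_spec(2 * s^2, 5 * s, 1.5, 20)
  p2 <- puck_state(10 * s, mobility = p1$mobility / s^3,
                   diffusivity = p1$diffusivity / s,
                   temperature = p1$temperature * s^2)
  # Delta Theta is an angle (dimensionless): evaluated at the rescaled
  # position it must equal the original profile
  xb <- c(2, 8, 14, 19)
  d1 <- crossing_profile(b1, p1, 1, 0.17, xb)
  d2 <- crossing_profile(b2, p2, 1 * s, 0.17, xb * s)
  expect_equal(d2, d1, tolerance = 1e-9)
})
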