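# Synthetic trajectory generators.

test_that("noiseless crossing equals the analytic profile exactly", {
  b <- default_bacterium()
  p <- default_puck()
  tr <- generate_crossing(b, p, 1, LAMBDA_REF, seed = 1,
                          noise = list(D_theta = 0, angle_sd = 0,
                                       position_sd = 0))
  expect_equal(tr$theta_rad,
               crossing_profile(b, p, 1, LAMBDA_REF, tr$xb_um),
               tolerance = 1e-12)
  expect_true(all(diff(tr$t_s) > 0))
  expect_identical(attr(tr, "W"), 1)
  # reproducibility
  tr2 <- generate_crossing(b, p, 1, LAMBDA_REF, seed = 3)
  tr3 <- generate_crossing(b, p, 1, LAMBDA_REF, seed = 3)
  expect_identical(tr2$theta_rad, tr3$theta_rad)
  expect_error(generate_crossing(b, p, 1, LAMBDA_REF, dt = 2), "too coarse")
  expect_error(generate_crossing(b, p, 1, LAMBDA_REF,
                                 noise = list(D_theta = -1)), ">= 0")
})

test_that("a torque-free swimmer leaves pure diffusion: MSAD recovers D", {
  b <- default_bacterium(motor_torque = 0, swim_speed = 2)  # slow -> long trace
  p <- default_puck()
  trs <- lapply(1:200, function(i)
    generate_crossing(b, p, 1, LAMBDA_REF, seed = i,
                      noise = list(D_theta = 6e-5, angle_sd = 0,
                                   position_sd = 0)))
  # stack as an ensemble on the common time grid
  ens <- data.frame(t_s = trs[[1]]$t_s)
  for (i in seq_along(trs))
    ens[[paste0("theta_rad_", i)]] <- trs[[i]]$theta_rad
  d <- estimate_diffusivity(ens)
  expect_equal(d$D, 6e-5, tolerance = 0.15)
})

test_that("ensemble mean of noisy crossings matches the analytic profile within 3 SE", {
  b <- default_bacterium()
  p <- default_puck()
  n <- 400
  trs <- lapply(seq_len(n), function(i)
    generate_crossing(b, p, 1, LAMBDA_REF, seed = 10000 + i))
  th <- vapply(trs, function(tr) tr$theta_rad, numeric(nrow(trs[[1]])))
  mu_hat <- rowMeans(th)
  se <- apply(th, 1, sd) / sqrt(n)
  det <- attr(trs[[1]], "theta_det")
  expect_true(all(abs(mu_hat - det) <= 3 * se + 1e-12))
})

test_that("passive generator is a Wiener process with the requested diffusivity", {
  expect_equal(generate_passive(0, 10, seed = 1)$theta_rad, rep(0, 101))
  s <- generate_passive(6e-5, 600, dt = 0.1, seed = 2, n_traces = 100)
  d <- estimate_diffusivity(s)
  expect_equal(d$D, 6e-5, tolerance = 0.15)
  # increments are Gaussian with mean zero (normality at alpha = 0.01)
  inc <- diff(s$theta_rad)
  set.seed(1)
  st <- shapiro.test(sample(inc, 5000))
  expect_gt(st$p.value, 0.01)
  expect_lt(abs(mean(inc)) / (sd(inc) / sqrt(length(inc))), 4)
  expect_identical(generate_passive(6e-5, 10, seed = 9)$theta_rad,
                   generate_passive(6e-5, 10, seed = 9)$theta_rad)
})

test_that("occupancy series steps its rate at entries and stays clockwise", {
  lay <- chamber_layout()
  occ <- generate_occupancy_series(lay, entry_rate = 0.05, duration = 400,
                                   seed = 21)
  expect_s3_class(occ, "occupancy_series")
  expect_true(all(occ$rates <= 0))
  expect_true(nrow(occ$events) >= 1)
  expect_true(all(occ$events$event == "enter"))
  # rates recompute from the event log: after the k-th entry the slope is the
  # chamber_rate of the accumulated occupancy
  p <- default_puck()
  for (k in seq_len(min(3, nrow(occ$events)))) {
    expected <- chamber_rate(
      chamber_layout(occupancy = occ$events$body_length_um[1:k]),
      NULL, p, 1, 0.17)
    idx <- round(occ$events$t_s[k] / 0.1) + 1   # step at which the entry acts
    expect_equal(occ$rates[idx], expected, tolerance = 1e-10)
  }
  # occupancy never exceeds the chamber count
  expect_lte(nrow(occ$events), lay$n_chambers)
  # zero entry rate -> pure diffusion
  quiet <- generate_occupancy_series(lay, entry_rate = 0, duration = 100,
                                     seed = 3)
  expect_equal(nrow(quiet$events), 0)
  expect_true(all(quiet$rates == 0))
  # reproducible
  occ2 <- generate_occupancy_series(lay, entry_rate = 0.05, duration = 400,
                                    seed = 21)
  expect_identical(occ$series$theta_rad, occ2$series$theta_rad)
})

test_that("four filled chambers rotate at the sum of the single rates", {
  p <- default_puck()
  lens <- c(3, 4, 5, 3.5)
  singles <- vapply(lens, function(l)
    chamber_rate(chamber_layout(occupancy = l), NULL, p, 1, 0.17), 0)
  full <- chamber_rate(chamber_layout(occupancy = lens), NULL, p, 1, 0.17)
  expect_equal(full, sum(singles), tolerance = 1e-14)
})
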