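# Boundary-element channel solver. Geometries are kept small (truncation
# 10-12 W at the coarsest admissible panels) so each dense solve runs in a
# few seconds; physical conclusions are h-independent properties.

test_that("zero-torque source gives the homogeneous solution", {
  sol <- solve_channel_flow(test_geometry(10), rotlet(c(0, 0, 0), c(0, 0, 0)))
  expect_true(all(sol$density == 0))
  u <- channel_velocity(sol, rbind(c(0, 0.2, 0.3), c(2, 0, 0)))
  expect_true(all(u == 0))
})

test_that("sources on or outside walls, or outside the window, are rejected", {
  g <- test_geometry(10)
  expect_error(solve_channel_flow(g, rotlet(c(0, 1, 0), c(1, 0, 0))),
               "on or outside")
  expect_error(solve_channel_flow(g, rotlet(c(0, 0, -1.2), c(1, 0, 0))),
               "on or outside")
  expect_error(solve_channel_flow(g, rotlet(c(4.9, 0, 0), c(1, 0, 0))),
               "window")
})

test_that("no-slip residual at collocation points is far below tolerance", {
  sol <- cached("sol_unit", solve_channel_flow(
    test_geometry(12), rotlet(c(0, 0, 0), c(1, 0, 0))))
  ns <- check_noslip(sol)
  expect_true(ns$ok)
  expect_lt(ns$max_residual, 1e-10)
})

test_that("solution is linear in the torque and superposes over sources", {
  g <- test_geometry(10)
  s1 <- cached("sol_lin1", solve_channel_flow(g, rotlet(c(1, 0, 0), c(1, 0, 0))))
  s2 <- cached("sol_lin2", solve_channel_flow(g, rotlet(c(-1, 0.2, 0), c(-2, 0, 0))))
  s12 <- cached("sol_lin12", solve_channel_flow(
    g, list(rotlet(c(1, 0, 0), c(1, 0, 0)), rotlet(c(-1, 0.2, 0), c(-2, 0, 0)))))
  pts <- rbind(c(0.3, 0.1, -0.4), c(2, -0.5, 0.5), c(-3, 0, 0.2))
  expect_equal(channel_velocity(s12, pts),
               channel_velocity(s1, pts) + channel_velocity(s2, pts),
               tolerance = 1e-8)
  # doubling the torque doubles the wall densities
  s2x <- solve_channel_flow(g, rotlet(c(1, 0, 0), c(2, 0, 0)))
  expect_equal(s2x$density, 2 * s1$density, tolerance = 1e-10)
})

test_that("duct flow is screened axially: speed at 5W is < 1% of speed at W", {
  sol <- cached("sol_unit", solve_channel_flow(
    test_geometry(12), rotlet(c(0, 0, 0), c(1, 0, 0))))
  p <- c(0.3, -0.2)
  uW <- channel_velocity(sol, c(1, p))
  u5 <- channel_velocity(sol, c(5, p))
  expect_lt(sqrt(sum(u5^2)) / sqrt(sum(uW^2)), 0.01)
})

test_that("a closed box transmits the rotlet torque to the walls and no net force", {
  # global balance: sum of panel moments of the wall traction (-density)
  # equals +Gamma_M xhat; the equal-and-opposite pair is force-free
  sol <- cached("sol_capped", solve_channel_flow(
    test_geometry(12), rotlet(c(0, 0, 0), c(1, 0, 0)), caps = TRUE))
  tq <- -sol$density * sol$panels$area          # traction * dS
  cen <- sol$panels$cen
  mom <- c(sum(cen[, 2] * tq[, 3] - cen[, 3] * tq[, 2]),
           sum(cen[, 3] * tq[, 1] - cen[, 1] * tq[, 3]),
           sum(cen[, 1] * tq[, 2] - cen[, 2] * tq[, 1]))
  expect_equal(mom[1], 1, tolerance = 0.05)     # O(h) quadrature error
  expect_equal(mom[2:3], c(0, 0), tolerance = 1e-10)
  pair <- solve_channel_flow(test_geometry(12),
                             list(rotlet(c(2, 0, 0), c(1, 0, 0)),
                                  rotlet(c(-2, 0, 0), c(-1, 0, 0))))
  f <- colSums(-pair$density * pair$panels$area)
  expect_lt(max(abs(f)), 1e-10)
})

test_that("closed chamber image system kills the normal velocity at the dead end", {
  g <- channel_geometry(1, truncation_factor = 12, panel_size = 0.25,
                        dead_end = 0)
  src <- list(rotlet(c(-1.5, 0, 0), c(1, 0, 0)),
              rotlet(c(-4.5, 0, 0), c(-1, 0, 0)))
  sol <- closed_chamber_solution(g, src)
  expect_length(sol$sources, 4)
  # probe the dead-end plane away from the singular images
  pts <- cbind(0, c(-0.5, 0, 0.4, 0.7), c(0.3, -0.6, 0.1, -0.2))
  un <- channel_velocity(sol, pts)[, 1]
  # scale: typical in-plane speed near the dipole
  uref <- sqrt(sum(channel_velocity(sol, c(-1.5, 0.5, 0))^2))
  expect_lt(max(abs(un)) / uref, 1e-10)
  expect_error(closed_chamber_solution(g, rotlet(c(2, 0, 0), c(1, 0, 0))),
               "beyond the dead end")
})

test_that("image-system chamber torque agrees with an explicit end-wall solve", {
  # same dipole, (a) image construction in an open duct vs (b) panelized end
  # walls (closed box) re-centred so one cap sits at the dead-end plane
  W <- 1; h <- 0.25; L <- 12
  src <- list(rotlet(c(-1.5, 0, 0), c(1, 0, 0)),
              rotlet(c(-4.5, 0, 0), c(-1, 0, 0)))
  gim <- channel_geometry(W, truncation_factor = L, panel_size = h,
                          dead_end = 0)
  sim <- closed_chamber_solution(gim, src)
  trim <- top_wall_traction(sim, axial_window = c(-0.45 * L, 0))
  gam_im <- as.numeric(puck_torque_from_traction(trim, c(-0.5, 0)))
  gex <- channel_geometry(W, truncation_factor = L, panel_size = h)
  shift <- lapply(src, function(s) rotlet(s$position + c(L / 2, 0, 0), s$torque))
  sex <- solve_channel_flow(gex, shift, caps = TRUE)
  trex <- top_wall_traction(sex, axial_window = c(-0.45 * L, 0) + L / 2)
  gam_ex <- as.numeric(puck_torque_from_traction(trex, c(L / 2 - 0.5, 0)))
  expect_lt(abs(gam_im - gam_ex) / abs(gam_ex), 0.20)
})

test_that("far from the dead end the transmitted torque approaches the open-channel value", {
  # the image contribution decays with distance: a dipole many W from the
  # dead end transmits (over the wall region it covers) the open value
  W <- 1; h <- 0.25; L <- 12
  src <- list(rotlet(c(-2.75, 0, 0), c(1, 0, 0)),
              rotlet(c(-4.25, 0, 0), c(-1, 0, 0)))
  gim <- channel_geometry(W, truncation_factor = L, panel_size = h,
                          dead_end = 0)
  sim <- closed_chamber_solution(gim, src)
  win <- c(-5, -0.5)
  trim <- top_wall_traction(sim, axial_window = win)
  gam_cl <- as.numeric(puck_torque_from_traction(trim, c(-3.5, 0)))
  gop <- channel_geometry(W, truncation_factor = L, panel_size = h)
  sop <- solve_channel_flow(gop, src)
  trop <- top_wall_traction(sop, axial_window = win)
  gam_op <- as.numeric(puck_torque_from_traction(trop, c(-3.5, 0)))
  expect_equal(gam_cl, gam_op, tolerance = 0.05)
})
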