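# Torque-transmission constant Lambda.
#
# Lambda couples a rotlet's microscopic torque to the vertical torque the
# duct's top wall transmits to the puck: Gamma_1 = -Lambda (x1-xC)/W Gamma_M.
# Equivalently Lambda = (W/Gamma_M) * integral over the top wall of
# mu dUy/dz dS for a unit axial rotlet anywhere on the centerline.

# --- symmetry-reduced solver -------------------------------------------------
# For a unit axial rotlet at the centre of a closed box, the solution is
# invariant under the order-8 group generated by 90-degree rotations about x
# and the mirror x -> -x. Unknowns reduce to the x>0 half of the top wall plus
# a quarter of the +x cap; all other panels are group images.

.rot_x <- function(k) {
  m <- diag(3)
  r <- rbind(c(1, 0, 0), c(0, 0, -1), c(0, 1, 0))
  for (i in seq_len(k %% 4)) m <- r %*% m
  m
}

.lambda_sym_group <- function() {
  g <- vector("list", 8)
  mir <- diag(c(-1, 1, 1))
  for (k in 0:3) {
    g[[2 * k + 1]] <- .rot_x(k)
    g[[2 * k + 2]] <- .rot_x(k) %*% mir
  }
  g
}

.lambda_at_h_sym <- function(W, L, h, mu, eps_factor = 2) {
  nx <- max(2L, 2L * round(L / h / 2))
  ny <- max(2L, 2L * round(2 * W / h / 2))
  dx <- L / nx
  dy <- 2 * W / ny
  eps <- dy / eps_factor
  xs <- (seq_len(nx / 2) - 0.5) * dx
  ys <- -W + (seq_len(ny) - 0.5) * dy
  top <- cbind(rep(xs, times = ny), rep(ys, each = nx / 2), W)
  yq <- (seq_len(ny / 2) - 0.5) * dy
  cap <- cbind(L / 2, rep(yq, times = ny / 2), rep(yq, each = ny / 2))
  cen <- rbind(top, cap)
  area <- c(rep(dx * dy, nrow(top)), rep(dy * dy, nrow(cap)))
  n <- nrow(cen)
  blocks <- vector("list", 9)
  dim(blocks) <- c(3, 3)
  for (a in 1:3) for (b in 1:3) blocks[[a, b]] <- matrix(0, n, n)
  e2 <- eps^2
  for (g in .lambda_sym_group()) {
    sc <- cen %*% t(g)
    ddx <- outer(cen[, 1], sc[, 1], "-")
    ddy <- outer(cen[, 2], sc[, 2], "-")
    ddz <- outer(cen[, 3], sc[, 3], "-")
    K <- .stokeslet_entries(ddx, ddy, ddz, e2)
    d <- list(ddx, ddy, ddz)
    for (a in 1:3) for (b in 1:3) {
      Gab <- d[[a]] * d[[b]] * K$H2
      if (a == b) Gab <- Gab + K$H1
      for (cc in 1:3) if (g[b, cc] != 0)
        blocks[[a, cc]] <- blocks[[a, cc]] + g[b, cc] * Gab
    }
  }
  w <- area / (8 * pi * mu)
  A <- matrix(0, 3 * n, 3 * n)
  for (a in 1:3) for (cc in 1:3)
    A[(a - 1) * n + 1:n, (cc - 1) * n + 1:n] <-
      sweep(blocks[[a, cc]], 2, w, "*")
  r3 <- (cen[, 1]^2 + cen[, 2]^2 + cen[, 3]^2)^1.5
  u0 <- cbind(0, -cen[, 3], cen[, 2]) / (8 * pi * mu * r3)  # unit Gamma_M = 1
  q <- matrix(solve(A, -c(u0[, 1], u0[, 2], u0[, 3])), n, 3)
  topi <- seq_len(nrow(top))
  # top wall = representatives plus their x-mirror images (q_y invariant);
  # traction on wall is -q, and Lambda = -(W/Gamma) * sum(t_y dS)
  lam <- W * 2 * sum(q[topi, 2] * area[topi])
  list(lambda = lam, n_unknowns = 3 * n, n_panels_full = 4 * nx * ny + 2 * ny^2)
}

.lambda_at_h_general <- function(W, L, h, mu, eps_factor = 2) {
  geom <- channel_geometry(W, truncation_factor = L / W, panel_size = h,
                           viscosity = mu)
  pan_h <- .panelize_channel(W, L, h, caps = TRUE)
  sol <- solve_channel_flow(geom, rotlet(c(0, 0, 0), c(1, 0, 0)), caps = TRUE,
                            regularization = pan_h$hy / eps_factor)
  top <- sol$panels$wall == "top"
  lam <- W * sum(sol$density[top, 2] * sol$panels$area[top])
  list(lambda = lam, n_unknowns = 3 * nrow(sol$panels$cen),
       n_panels_full = nrow(sol$panels$cen))
}

#' Compute the dimensionless torque-transmission constant
#'
#' Places a unit axial rotlet on the centerline of a closed panelized duct,
#' solves the no-slip boundary-integral system at a sequence of panel sizes,
#' evaluates the top-wall traction integral of the transmission law, and
#' Richardson-extrapolates in panel size. With the regularization tied to the
#' panel size the leading error is a power of h whose order is estimated from
#' the refinement sequence itself (clamped to [0.5, 2]) when three or more
#' levels are available.
#'
#' Lambda is dimensionless and independent of every physical parameter
#' (including the half-width), which the test suite asserts at two scales.
#'
#' @param geometry A [channel_geometry()]; its half-width, truncation length
#'   and viscosity are used. The truncation should be at least 20 half-widths.
#' @param refinement_levels Numeric vector of panel sizes h (um), coarsest
#'   first; at least 2. Default `W / c(4, 6, 8, 10)`.
#' @param use_symmetry Use the 8-fold symmetry-reduced solver (default). The
#'   general dense solver gives identical panelizations and is used for
#'   cross-validation in the tests.
#' @param eps_factor Blob parameter as `panel_size / eps_factor` (default 2).
#' @return An object of class `"lambda_result"`: `value` (extrapolated),
#'   `uncertainty`, and a per-level data frame `levels`.
#' @export
#' @examples
#' \donttest{
#' geom <- channel_geometry(1, truncation_factor = 20)
#' compute_lambda(geom, refinement_levels = c(1 / 4, 1 / 6))
#' }
compute_lambda <- function(geometry = channel_geometry(1, truncation_factor = 20),
                           refinement_levels = NULL,
                           use_symmetry = TRUE, eps_factor = 2) {
  stopifnot(inherits(geometry, "channel_geometry"))
  W <- geometry$half_width
  L <- geometry$length
  mu <- geometry$viscosity
  if (is.null(refinement_levels))
    refinement_levels <- W / c(4, 6, 8, 10)
  h <- sort(as.numeric(refinement_levels), decreasing = TRUE)
  if (length(h) < 2)
    stop("need at least 2 refinement levels for extrapolation", call. = FALSE)
  if (any(h > W / 4 + 1e-12))
    stop("refinement levels must satisfy h <= W/4", call. = FALSE)
  res <- lapply(h, function(hh) {
    if (use_symmetry) .lambda_at_h_sym(W, L, hh, mu, eps_factor)
    else .lambda_at_h_general(W, L, hh, mu, eps_factor)
  })
  lam <- vapply(res, `[[`, 0, "lambda")
  k <- length(lam)
  d <- diff(lam)
  if (k >= 3) {
    if (any(sign(d) != sign(d[1])) || any(diff(abs(d)) > 0.2 * abs(d[-(k - 1)])))
      stop(paste0("refinement sequence not converging; per-level Lambda: ",
                  paste(sprintf("h=%.4g: %.5f", h, lam), collapse = "; ")),
           call. = FALSE)
    # empirical order from the last three levels
    h3 <- h[(k - 2):k]
    d2 <- d[(k - 2):(k - 1)]
    f <- function(p) (h3[1]^p - h3[2]^p) / (h3[2]^p - h3[3]^p) - d2[1] / d2[2]
    p <- tryCatch(stats::uniroot(f, c(0.3, 3))$root, error = function(e) 1)
    p <- min(max(p, 0.5), 2)
  } else p <- 1
  extrap <- function(pp) {
    lam[k] + (lam[k] - lam[k - 1]) * h[k]^pp / (h[k - 1]^pp - h[k]^pp)
  }
  value <- extrap(p)
  unc <- max(abs(value - extrap(1)), abs(value - lam[k]) / 4)
  structure(list(value = value, uncertainty = unc, order = p,
                 levels = data.frame(h_um = h, lambda = lam,
                                     n_unknowns = vapply(res, function(r)
                                       as.integer(r$n_unknowns), 0L)),
                 geometry = geometry, use_symmetry = use_symmetry),
            class = "lambda_result")
}

#' @export
print.lambda_result <- function(x, ...) {
  cat(sprintf("torque-transmission constant Lambda = %.4f +/- %.4f\n",
              x$value, x$uncertainty))
  cat(sprintf("  extrapolated at order h^%.2f from %d refinement level(s):\n",
              x$order, nrow(x$levels)))
  for (i in seq_len(nrow(x$levels)))
    cat(sprintf("    h = %.4g um: Lambda = %.5f  (%d unknowns)\n",
                x$levels$h_um[i], x$levels$lambda[i], x$levels$n_unknowns[i]))
  invisible(x)
}

#' @export
plot.lambda_result <- function(x, ...) {
  plot(x$levels$h_um, x$levels$lambda, xlab = "panel size h (um)",
       ylab = expression(Lambda), pch = 19,
       ylim = range(c(x$levels$lambda, x$value)), ...)
  abline(h = x$value, lty = 2)
  invisible(x)
}

#' Closed-chamber torque-transmission correction
#'
#' Dimensionless multiplier on the open-channel dipole torque when the channel
#' is closed by a dead-end wall near the puck centre. Computed numerically:
#' the dipole plus its image system (see [closed_chamber_solution()]) is
#' solved in the duct, and the transmitted torque is the moment of the
#' top-wall traction over the physical half of the wall (x <= dead end),
#' normalized by the open-channel torque of the same dipole.
#'
#' The result depends only on the dimensionless distances (dipole length,
#' body position, puck radius relative to W), and is cached per parameter set
#' within a session.
#'
#' @param W Channel half-width (um).
#' @param puck_radius Puck radius R (um); the puck centre is at distance R
#'   from the channel entrance.
#' @param dead_end_offset Distance d from puck centre to the dead-end wall
#'   (um), default 0.5.
#' @param body_length,dipole_ratio Bacterium body length and dipole ratio; the
#'   body centre is placed half a body length from the dead end.
#' @param panel_size Panel size for the numerical solve (um).
#' @param truncation_factor Axial truncation for the solve.
#' @return Dimensionless correction factor (torque_closed / torque_open).
#' @export
closed_chamber_correction <- function(W, puck_radius, dead_end_offset = 0.5,
                                      body_length = 5, dipole_ratio = 1.5,
                                      panel_size = W / 4,
                                      truncation_factor = 24) {
  key <- paste(signif(c(W, puck_radius, dead_end_offset, body_length,
                        dipole_ratio, panel_size, truncation_factor), 8),
               collapse = "|")
  hit <- .tp_cache[[key]]
  if (!is.null(hit)) return(hit)
  mu <- tp_constants$water_viscosity_pN_s_per_um2
  # coordinates with the dead-end wall at x = 0; the puck centre sits a
  # distance d before it and the channel entrance at x = -2R + d
  geom <- channel_geometry(W, truncation_factor = truncation_factor,
                           panel_size = panel_size, viscosity = mu,
                           dead_end = 0)
  ld <- dipole_ratio * body_length
  x1 <- -body_length / 2       # leading (body) rotlet, nose at the dead end
  x2 <- x1 - ld                # trailing (flagellar) rotlet
  src <- list(rotlet(c(x1, 0, 0), c(1, 0, 0)),
              rotlet(c(x2, 0, 0), c(-1, 0, 0)))
  sol <- closed_chamber_solution(geom, src)
  tr <- top_wall_traction(sol, axial_window = c(-0.45 * geom$length, 0))
  xc <- -dead_end_offset
  gam_closed <- as.numeric(puck_torque_from_traction(tr, c(xc, 0)))
  # open-channel reference with the same numerical machinery
  geo2 <- channel_geometry(W, truncation_factor = truncation_factor,
                           panel_size = panel_size, viscosity = mu)
  solo <- solve_channel_flow(geo2, list(rotlet(c(ld / 2, 0, 0), c(1, 0, 0)),
                                        rotlet(c(-ld / 2, 0, 0), c(-1, 0, 0))))
  tro <- top_wall_traction(solo)
  gam_open <- as.numeric(puck_torque_from_traction(tro, c(0, 0)))
  out <- gam_closed / gam_open
  assign(key, out, envir = .tp_cache)
  out
}

.tp_cache <- new.env(parent = emptyenv())
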