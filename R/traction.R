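#' Viscous traction on the channel's top wall
#'
#' The top wall z = +W belongs to the puck, so the in-plane viscous traction
#' there, `t = -mu (dUx/dz, dUy/dz)`, is the carrier of torque transmission
#' from the swimmer to the disc.
#'
#' Three evaluation routes are provided. `"fd"` (default) one-sidedly
#' differences the velocity evaluator just below the wall; because the wall
#' kernels are regularized over a blob scale epsilon, the sampling window is
#' placed at depth `2 * eps` (below the smeared traction layer) with step
#' `h/4`. `"analytic"` differentiates the regularized kernels exactly at the
#' same depth and must agree with `"fd"` to a couple of percent. `"density"`
#' uses the exact identity traction = -(wall force density), valid when the
#' panelization is closed (capped ends), in which case the exterior field
#' vanishes identically; its grid is the top-wall panel centres.
#'
#' @param solution A `"channel_flow"`.
#' @param axial_window Length-2 numeric, x-interval to cover (um). Default:
#'   the central 80% of the truncation window.
#' @param resolution Grid spacing (um); default the panel size.
#' @param method One of `"fd"`, `"analytic"`, `"density"`.
#' @return An object of class `"wall_traction_field"`: data frame with columns
#'   `x_um`, `y_um`, `tx_pN_per_um2`, `ty_pN_per_um2`, `weight_um2` plus
#'   metadata attributes.
#' @export
top_wall_traction <- function(solution, axial_window = NULL, resolution = NULL,
                              method = c("fd", "analytic", "density")) {
  stopifnot(inherits(solution, "channel_flow"))
  method <- match.arg(method)
  pan <- solution$panels
  W <- pan$W
  x0 <- pan$x0
  if (is.null(axial_window))
    axial_window <- x0 + c(-0.4, 0.4) * pan$L
  if (length(axial_window) != 2 || diff(axial_window) <= 0)
    stop("`axial_window` must be an increasing length-2 interval", call. = FALSE)
  if (axial_window[1] < x0 - pan$L / 2 - 1e-9 ||
      axial_window[2] > x0 + pan$L / 2 + 1e-9)
    stop("axial window exceeds the truncation window", call. = FALSE)

  if (method == "density") {
    top <- pan$wall == "top" & pan$cen[, 1] >= axial_window[1] &
      pan$cen[, 1] <= axial_window[2]
    df <- data.frame(x_um = pan$cen[top, 1], y_um = pan$cen[top, 2],
                     tx_pN_per_um2 = -solution$density[top, 1],
                     ty_pN_per_um2 = -solution$density[top, 2],
                     weight_um2 = pan$area[top])
    if (!pan$caps)
      attr(df, "note") <- "density traction on an open panelization is approximate"
  } else {
    h <- if (is.null(resolution)) pan$h else resolution
    check_scalar(h, "resolution", positive = TRUE)
    nx <- max(2L, ceiling(diff(axial_window) / h))
    ny <- max(2L, ceiling(2 * W / h))
    xs <- axial_window[1] + (seq_len(nx) - 0.5) * diff(axial_window) / nx
    ys <- -W + (seq_len(ny) - 0.5) * 2 * W / ny
    gx <- rep(xs, times = ny)
    gy <- rep(ys, each = nx)
    wgt <- rep(diff(axial_window) / nx * 2 * W / ny, nx * ny)
    depth <- 2 * solution$eps
    if (method == "fd") {
      step <- pan$h / 4
      p1 <- cbind(gx, gy, W - depth)
      p2 <- cbind(gx, gy, W - depth - step)
      u1 <- channel_velocity(solution, p1)
      u2 <- channel_velocity(solution, p2)
      dudz <- (u1 - u2) / step
    } else {
      dudz <- .velocity_z_derivative(solution, cbind(gx, gy, W - depth))
    }
    df <- data.frame(x_um = gx, y_um = gy,
                     tx_pN_per_um2 = -solution$mu * dudz[, 1],
                     ty_pN_per_um2 = -solution$mu * dudz[, 2],
                     weight_um2 = wgt)
  }
  structure(df, class = c("wall_traction_field", "data.frame"),
            W = W, method = method, axial_window = axial_window)
}

# Analytic z-derivative of (rotlet + regularized single layer) velocity.
.velocity_z_derivative <- function(solution, pts) {
  mu <- solution$mu
  out <- matrix(0, nrow(pts), 3)
  for (s in solution$sources) {
    if (all(s$torque == 0)) next
    d1 <- pts[, 1] - s$position[1]
    d2 <- pts[, 2] - s$position[2]
    d3 <- pts[, 3] - s$position[3]
    r2 <- d1^2 + d2^2 + d3^2
    r3 <- r2^1.5
    r5 <- r2^2.5
    g <- s$torque
    cx <- g[2] * d3 - g[3] * d2
    cy <- g[3] * d1 - g[1] * d3
    cz <- g[1] * d2 - g[2] * d1
    # d/dz of (Gamma x d)/r^3: (Gamma x zhat)/r^3 - 3 d3 (Gamma x d)/r^5
    out <- out + cbind(g[2] / r3 - 3 * d3 * cx / r5,
                       -g[1] / r3 - 3 * d3 * cy / r5,
                       -3 * d3 * cz / r5) / (8 * pi * mu)
  }
  cen <- solution$panels$cen
  q <- solution$density
  if (any(q != 0)) {
    w <- solution$panels$area / (8 * pi * mu)
    e2 <- solution$eps^2
    chunk <- 2048L
    idx <- split(seq_len(nrow(pts)), ceiling(seq_len(nrow(pts)) / chunk))
    for (I in idx) {
      dx <- outer(pts[I, 1], cen[, 1], "-")
      dy <- outer(pts[I, 2], cen[, 2], "-")
      dz <- outer(pts[I, 3], cen[, 3], "-")
      r2 <- dx * dx + dy * dy + dz * dz
      Re3 <- (r2 + e2)^1.5
      Re5 <- (r2 + e2)^2.5
      H1 <- (r2 + 2 * e2) / Re3
      H2 <- 1 / Re3
      dH1 <- 2 * dz / Re3 - 3 * dz * (r2 + 2 * e2) / Re5
      dH2 <- -3 * dz / Re5
      fd  <- sweep(dx, 2, q[, 1] * w, "*") + sweep(dy, 2, q[, 2] * w, "*") +
        sweep(dz, 2, q[, 3] * w, "*")
      qw1 <- q[, 1] * w; qw2 <- q[, 2] * w; qw3 <- q[, 3] * w
      out[I, 1] <- out[I, 1] + dH1 %*% qw1 +
        rowSums(dH2 * fd * dx + H2 * sweep(dx, 2, qw3, "*"))
      out[I, 2] <- out[I, 2] + dH1 %*% qw2 +
        rowSums(dH2 * fd * dy + H2 * sweep(dy, 2, qw3, "*"))
      out[I, 3] <- out[I, 3] + dH1 %*% qw3 +
        rowSums(dH2 * fd * dz + H2 * (sweep(dz, 2, qw3, "*") + fd))
    }
  }
  out
}

#' Vertical torque on the puck from a wall-traction field
#'
#' Quadrature of the moment `(r - r_C) x t` about the puck centre, keeping the
#' z-component: `integral[(x - xC) t_y - (y - yC) t_x] dS`. If the traction has
#' not decayed at the axial ends of the covered window (relative to its peak),
#' the result carries `attr(, "support_warning") = TRUE`.
#'
#' @param traction A `"wall_traction_field"`.
#' @param puck_center Length-2 numeric `(xC, yC)` (um).
#' @param decay_tol Relative edge/peak traction magnitude above which the
#'   support is flagged as truncated (default 0.01).
#' @return Signed vertical torque (pN um) with attribute `support_warning`.
#' @export
puck_torque_from_traction <- function(traction, puck_center = c(0, 0),
                                      decay_tol = 0.01) {
  stopifnot(inherits(traction, "wall_traction_field"))
  if (length(puck_center) != 2)
    stop("`puck_center` must be (xC, yC)", call. = FALSE)
  tx <- traction$tx_pN_per_um2
  ty <- traction$ty_pN_per_um2
  tot <- sum(((traction$x_um - puck_center[1]) * ty -
                (traction$y_um - puck_center[2]) * tx) * traction$weight_um2)
  mag <- sqrt(tx^2 + ty^2)
  win <- attr(traction, "axial_window")
  xs <- sort(unique(traction$x_um))
  cell <- if (length(xs) > 1) median(diff(xs)) else diff(win)
  band <- max(0.05 * diff(win), 1.1 * cell)
  edge <- traction$x_um < win[1] + band | traction$x_um > win[2] - band
  warn <- FALSE
  if (any(edge) && max(mag) > 0)
    warn <- max(mag[edge]) / max(mag) > decay_tol
  structure(tot, support_warning = warn)
}
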