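# Flat rectangular panelization of the duct walls.
#
# Walls carry constant force densities per panel, collocated at panel centres.
# Panel centres never sit on the symmetry axes (offset by h/2), which the
# symmetry-reduced fast path of compute_lambda() relies on.

.panelize_channel <- function(W, L, h, caps = FALSE, x0 = 0) {
  nx <- max(2L, 2L * round(L / h / 2))      # even count along x
  ny <- max(2L, 2L * round(2 * W / h / 2))  # even count across
  dx <- L / nx
  dy <- 2 * W / ny
  xs <- x0 - L / 2 + (seq_len(nx) - 0.5) * dx
  ys <- -W + (seq_len(ny) - 0.5) * dy
  gx <- rep(xs, times = ny)
  gy <- rep(ys, each = nx)
  cen <- rbind(cbind(gx, gy, W), cbind(gx, gy, -W),
               cbind(gx, W, gy), cbind(gx, -W, gy))
  colnames(cen) <- c("x", "y", "z")
  wall <- rep(c("top", "bottom", "side_y_pos", "side_y_neg"), each = nx * ny)
  area <- rep(dx * dy, nrow(cen))
  if (caps) {
    g1 <- rep(ys, times = ny)
    g2 <- rep(ys, each = ny)
    cen <- rbind(cen, cbind(x0 + L / 2, g1, g2), cbind(x0 - L / 2, g1, g2))
    wall <- c(wall, rep(c("cap_pos", "cap_neg"), each = ny * ny))
    area <- c(area, rep(dy * dy, 2 * ny * ny))
  }
  list(cen = cen, wall = wall, area = area, h = h, hx = dx, hy = dy,
       nx = nx, ny = ny, W = W, L = L, x0 = x0, caps = caps)
}

# Dense collocation matrix for the regularized-Stokeslet layer, component-major
# ordering ([all x | all y | all z]). Chunked row assembly bounds temporary
# memory at ~6 * chunk * n doubles.
.assemble_panel_matrix <- function(pan, mu, eps, chunk = 768L) {
  cen <- pan$cen
  n <- nrow(cen)
  w <- pan$area / (8 * pi * mu)
  e2 <- eps^2
  A <- matrix(0, 3 * n, 3 * n)
  idx <- split(seq_len(n), ceiling(seq_len(n) / chunk))
  for (I in idx) {
    dx <- outer(cen[I, 1], cen[, 1], "-")
    dy <- outer(cen[I, 2], cen[, 2], "-")
    dz <- outer(cen[I, 3], cen[, 3], "-")
    K <- .stokeslet_entries(dx, dy, dz, e2)
    H1 <- sweep(K$H1, 2, w, "*")
    H2 <- sweep(K$H2, 2, w, "*")
    A[I, 1:n]                 <- H1 + dx * dx * H2
    A[I, n + 1:n]             <- dx * dy * H2
    A[I, 2 * n + 1:n]         <- dx * dz * H2
    A[n + I, 1:n]             <- dy * dx * H2
    A[n + I, n + 1:n]         <- H1 + dy * dy * H2
    A[n + I, 2 * n + 1:n]     <- dy * dz * H2
    A[2 * n + I, 1:n]         <- dz * dx * H2
    A[2 * n + I, n + 1:n]     <- dz * dy * H2
    A[2 * n + I, 2 * n + 1:n] <- H1 + dz * dz * H2
  }
  A
}
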