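# Independent Stokes oracle, deliberately built on different numerics from the
# package's boundary-element path: Fourier modes along the channel axis
# (periodic box) and a 2D staggered (MAC) finite-difference Stokes solve in
# the cross-section, no-slip at y, z = +-W, with a Gaussian-regularized rotlet
# forcing curl((Gamma/2) delta_eps xhat). Used only to cross-check velocities
# and the torque-transmission constant.

or_lap_refl <- function(m, d) {
  M <- Matrix::bandSparse(m, m, k = c(-1, 0, 1),
                          diagonals = list(rep(1, m - 1), rep(-2, m),
                                           rep(1, m - 1)))
  M[1, 1] <- -3
  M[m, m] <- -3
  M / d^2
}

or_lap_face <- function(m, d) {
  Matrix::bandSparse(m, m, k = c(-1, 0, 1),
                     diagonals = list(rep(1, m - 1), rep(-2, m),
                                      rep(1, m - 1))) / d^2
}

# One axial-wavenumber 2D Stokes solve. Unknowns (y index fastest):
# u (n x n cell centres), v ((n-1) x n y-faces), w (n x (n-1) z-faces),
# p (n x n). Complex system solved as a real-doubled sparse system.
or_stokes_mode <- function(n, dy, k, mu, gx, gv, gw, pin = FALSE) {
  In <- Matrix::Diagonal(n)
  Inm <- Matrix::Diagonal(n - 1)
  Lc <- Matrix::kronecker(or_lap_refl(n, dy), In) +
    Matrix::kronecker(In, or_lap_refl(n, dy))
  Lv <- Matrix::kronecker(or_lap_refl(n, dy), Inm) +
    Matrix::kronecker(In, or_lap_face(n - 1, dy))
  Lw <- Matrix::kronecker(or_lap_face(n - 1, dy), In) +
    Matrix::kronecker(Inm, or_lap_refl(n, dy))
  Dv1 <- Matrix::sparseMatrix(i = c(1:(n - 1), 2:n), j = c(1:(n - 1), 1:(n - 1)),
                              x = c(rep(1, n - 1), rep(-1, n - 1)),
                              dims = c(n, n - 1)) / dy
  Dv <- Matrix::kronecker(In, Dv1)
  Dw <- Matrix::kronecker(Dv1, In)
  Gv <- -Matrix::t(Dv)
  Gw <- -Matrix::t(Dw)
  nu <- n * n; nv <- (n - 1) * n; nw <- n * (n - 1); np <- n * n
  Au <- mu * (Lc - k^2 * Matrix::Diagonal(nu))
  Av <- mu * (Lv - k^2 * Matrix::Diagonal(nv))
  Aw <- mu * (Lw - k^2 * Matrix::Diagonal(nw))
  Z <- function(a, b) Matrix::Matrix(0, a, b, sparse = TRUE)
  A <- rbind(
    cbind(Au, Z(nu, nu), Z(nu, nv), Z(nu, nv), Z(nu, nw), Z(nu, nw),
          Z(nu, np), k * Matrix::Diagonal(np)),
    cbind(Z(nu, nu), Au, Z(nu, nv), Z(nu, nv), Z(nu, nw), Z(nu, nw),
          -k * Matrix::Diagonal(np), Z(nu, np)),
    cbind(Z(nv, nu), Z(nv, nu), Av, Z(nv, nv), Z(nv, nw), Z(nv, nw),
          -Gv, Z(nv, np)),
    cbind(Z(nv, nu), Z(nv, nu), Z(nv, nv), Av, Z(nv, nw), Z(nv, nw),
          Z(nv, np), -Gv),
    cbind(Z(nw, nu), Z(nw, nu), Z(nw, nv), Z(nw, nv), Aw, Z(nw, nw),
          -Gw, Z(nw, np)),
    cbind(Z(nw, nu), Z(nw, nu), Z(nw, nv), Z(nw, nv), Z(nw, nw), Aw,
          Z(nw, np), -Gw),
    cbind(Z(np, nu), -k * Matrix::Diagonal(nu), Dv, Z(np, nv), Dw, Z(np, nw),
          Z(np, np), Z(np, np)),
    cbind(k * Matrix::Diagonal(nu), Z(np, nu), Z(np, nv), Dv, Z(np, nw), Dw,
          Z(np, np), Z(np, np)))
  rhs <- c(-Re(gx), -Im(gx), -Re(gv), -Im(gv), -Re(gw), -Im(gw),
           rep(0, 2 * np))
  if (pin) {
    i1 <- 2 * (nu + nv + nw) + 1
    i2 <- i1 + np
    A[i1, ] <- 0; A[i1, 2 * (nu + nv + nw) + 1] <- 1
    A[i2, ] <- 0; A[i2, 2 * (nu + nv + nw) + np + 1] <- 1
    rhs[i1] <- 0; rhs[i2] <- 0
  }
  sol <- as.numeric(Matrix::solve(A, rhs))
  list(u = complex(real = sol[1:nu], imaginary = sol[nu + 1:nu]),
       v = complex(real = sol[2 * nu + 1:nv],
                   imaginary = sol[2 * nu + nv + 1:nv]),
       w = complex(real = sol[2 * nu + 2 * nv + 1:nw],
                   imaginary = sol[2 * nu + 2 * nv + nw + 1:nw]))
}

# Full-mode solve for an axial rotlet at `src` in a periodic box of length Lx.
oracle_solve <- function(W, Lx, Nx, n, mu, gamma, src = c(Lx / 2, 0, 0),
                         blob = NULL) {
  dy <- 2 * W / n
  dx <- Lx / Nx
  if (is.null(blob)) blob <- 1.5 * max(dy, dx)
  xs <- (seq_len(Nx) - 1) * dx
  yc <- -W + (seq_len(n) - 0.5) * dy
  yf <- -W + seq_len(n - 1) * dy
  d3 <- function(x, y, z)
    exp(-(x^2 + y^2 + z^2) / (2 * blob^2)) / ((2 * pi)^1.5 * blob^3)
  gv_field <- array(0, c(Nx, n - 1, n))
  gw_field <- array(0, c(Nx, n, n - 1))
  for (i in seq_len(Nx)) {
    xd <- xs[i] - src[1]
    xd <- xd - Lx * round(xd / Lx)
    Yf <- matrix(yf - src[2], n - 1, n)
    Zc <- matrix(yc - src[3], n - 1, n, byrow = TRUE)
    gv_field[i, , ] <- (gamma / 2) * (-Zc / blob^2) * d3(xd, Yf, Zc)
    Yc <- matrix(yc - src[2], n, n - 1)
    Zf <- matrix(yf - src[3], n, n - 1, byrow = TRUE)
    gw_field[i, , ] <- -(gamma / 2) * (-Yc / blob^2) * d3(xd, Yc, Zf)
  }
  gv_hat <- apply(gv_field, c(2, 3), fft) / Nx
  gw_hat <- apply(gw_field, c(2, 3), fft) / Nx
  modes <- vector("list", Nx / 2 + 1)
  for (m in 0:(Nx / 2)) {
    k <- 2 * pi * m / Lx
    modes[[m + 1]] <- or_stokes_mode(
      n, dy, k, mu, gx = rep(0 + 0i, n * n),
      gv = as.vector(gv_hat[m + 1, , ]), gw = as.vector(gw_hat[m + 1, , ]),
      pin = (m == 0))
  }
  list(modes = modes, W = W, Lx = Lx, Nx = Nx, n = n, dy = dy, mu = mu,
       yc = yc, yf = yf, src = src)
}

# velocity at points (nearest cross-section cell, spectral in x)
oracle_velocity <- function(os, pts) {
  n <- os$n
  Nx <- os$Nx
  out <- matrix(0, nrow(pts), 3)
  for (r in seq_len(nrow(pts))) {
    jy <- which.min(abs(os$yc - pts[r, 2]))
    jz <- which.min(abs(os$yc - pts[r, 3]))
    uu <- vv <- ww <- 0 + 0i
    for (m in 0:(Nx - 1)) {
      mm <- if (m <= Nx / 2) m else m - Nx
      k <- 2 * pi * mm / os$Lx
      sol <- if (m <= Nx / 2) os$modes[[m + 1]]
      else lapply(os$modes[[Nx - m + 1]], Conj)
      um <- matrix(sol$u, n, n)[jy, jz]
      vpad <- rbind(0, matrix(sol$v, n - 1, n), 0)
      vm <- (vpad[jy, jz] + vpad[jy + 1, jz]) / 2
      wpad <- cbind(0, matrix(sol$w, n, n - 1), 0)
      wm <- (wpad[jy, jz] + wpad[jy, jz + 1]) / 2
      ph <- exp(1i * k * pts[r, 1])
      uu <- uu + um * ph
      vv <- vv + vm * ph
      ww <- ww + wm * ph
    }
    out[r, ] <- Re(c(uu, vv, ww))
  }
  out
}

# Lambda needs only the x-averaged (mode 0) field: a single 2D Stokes solve
# with the analytically x-integrated Gaussian forcing (a 2D rotlet line
# density); the box length drops out. dUy/dz at the wall via a one-sided
# quadratic through the no-slip value.
oracle_lambda <- function(W, n, mu = 1e-3, blob = NULL, gamma_lin = 1) {
  dy <- 2 * W / n
  if (is.null(blob)) blob <- 1.5 * dy
  yc <- -W + (seq_len(n) - 0.5) * dy
  yf <- -W + seq_len(n - 1) * dy
  d2 <- function(y, z) exp(-(y^2 + z^2) / (2 * blob^2)) / (2 * pi * blob^2)
  Yf <- matrix(yf, n - 1, n)
  Zc <- matrix(yc, n - 1, n, byrow = TRUE)
  gv <- (gamma_lin / 2) * (-Zc / blob^2) * d2(Yf, Zc)
  Yc <- matrix(yc, n, n - 1)
  Zf <- matrix(yf, n, n - 1, byrow = TRUE)
  gw <- -(gamma_lin / 2) * (-Yc / blob^2) * d2(Yc, Zf)
  sol <- or_stokes_mode(n, dy, k = 0, mu, gx = rep(0 + 0i, n * n),
                        gv = as.vector(gv) + 0i, gw = as.vector(gw) + 0i,
                        pin = TRUE)
  v0 <- matrix(Re(sol$v), n - 1, n)
  dUydz <- -(9 * v0[, n] - v0[, n - 1]) / (3 * dy)
  (W * mu / gamma_lin) * sum(dUydz) * dy
}
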