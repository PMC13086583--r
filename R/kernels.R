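#' Free-space rotlet velocity field
#'
#' Velocity of the unbounded point-torque solution,
#' `U = Gamma x (r - r0) / (8 pi mu |r - r0|^3)`. This is the source term that
#' the wall corrections of [solve_channel_flow()] cancel at the boundaries.
#'
#' @param torque Numeric 3-vector, point torque Gamma (pN um).
#' @param source Numeric 3-vector, rotlet position (um).
#' @param field_point Numeric 3-vector or n x 3 matrix of evaluation points (um).
#' @param viscosity Dynamic viscosity (pN s um^-2).
#' @return Velocity (um/s): a 3-vector, or an n x 3 matrix if `field_point`
#'   is a matrix.
#' @export
#' @examples
#' # torque 8*pi*mu along x at the origin, probe on the y axis: velocity +z
#' mu <- 1e-3
#' free_space_rotlet_velocity(c(8 * pi * mu, 0, 0), c(0, 0, 0), c(0, 1, 0), mu)
free_space_rotlet_velocity <- function(torque, source, field_point,
                                       viscosity = tp_constants$water_viscosity_pN_s_per_um2) {
  check_scalar(viscosity, "viscosity", positive = TRUE)
  one <- is.null(dim(field_point))
  pts <- if (one) matrix(field_point, 1, 3) else as.matrix(field_point)
  if (ncol(pts) != 3) stop("`field_point` must have 3 columns", call. = FALSE)
  d1 <- pts[, 1] - source[1]
  d2 <- pts[, 2] - source[2]
  d3 <- pts[, 3] - source[3]
  r2 <- d1 * d1 + d2 * d2 + d3 * d3
  if (any(r2 == 0))
    stop("field point coincides with the rotlet position (singular)",
         call. = FALSE)
  r3 <- r2^1.5
  u <- cbind(torque[2] * d3 - torque[3] * d2,
             torque[3] * d1 - torque[1] * d3,
             torque[1] * d2 - torque[2] * d1) / (8 * pi * viscosity * r3)
  if (one) drop(u) else u
}

# Regularized Stokeslet (Cortez blob) velocity kernel, vectorized over
# point/source pairs expressed as offset component matrices. Returns the six
# distinct tensor entries; the blob parameter eps smooths the 1/r singularity
# over the panel scale.
.stokeslet_entries <- function(dx, dy, dz, eps2) {
  r2 <- dx * dx + dy * dy + dz * dz
  Re3 <- (r2 + eps2)^1.5
  H1 <- (r2 + 2 * eps2) / Re3
  H2 <- 1 / Re3
  list(H1 = H1, H2 = H2)
}

# Velocity at points `pts` induced by panel force densities q (n x 3) with
# quadrature weights w = area/(8 pi mu), blob eps. Chunked to bound memory.
.panel_velocity <- function(pts, cen, q, w, eps, chunk = 2048L) {
  m <- nrow(pts)
  out <- matrix(0, m, 3)
  e2 <- eps^2
  idx <- split(seq_len(m), ceiling(seq_len(m) / chunk))
  for (I in idx) {
    dx <- outer(pts[I, 1], cen[, 1], "-")
    dy <- outer(pts[I, 2], cen[, 2], "-")
    dz <- outer(pts[I, 3], cen[, 3], "-")
    K <- .stokeslet_entries(dx, dy, dz, e2)
    fd <- sweep(dx, 2, q[, 1] * w, "*") + sweep(dy, 2, q[, 2] * w, "*") +
      sweep(dz, 2, q[, 3] * w, "*")
    # fd currently holds sum over components of d_b q_b w (still a matrix per
    # source); multiply H2 then row-sum
    out[I, 1] <- K$H1 %*% (q[, 1] * w) + rowSums(K$H2 * fd * dx)
    out[I, 2] <- K$H1 %*% (q[, 2] * w) + rowSums(K$H2 * fd * dy)
    out[I, 3] <- K$H1 %*% (q[, 3] * w) + rowSums(K$H2 * fd * dz)
  }
  out
}
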