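#' Solve Stokes flow driven by rotlets in a no-slip square channel
#'
#' First-kind boundary-integral solve with regularized-Stokeslet kernels on
#' flat rectangular panels (constant density per panel, collocation at panel
#' centres). The flow is the free-space field of the supplied rotlets plus a
#' single-layer wall correction that cancels it on the walls, enforcing no
#' slip. The solution is linear in the rotlet torques, so superposition over
#' `sources` holds to solver tolerance.
#'
#' @param geometry A [channel_geometry()].
#' @param sources A single [rotlet()] or a list of rotlets. All sources must
#'   lie strictly inside the duct cross-section and truncation window.
#' @param caps Close the truncated ends with panelized end walls? Open
#'   (panel-free) ends are the default realization of an "infinite" channel;
#'   closed caps make the wall-density/traction identity exact and are used
#'   internally by [compute_lambda()].
#' @param regularization Blob parameter epsilon (um); default `panel_size / 2`.
#' @param tol_noslip Relative no-slip residual tolerance used by
#'   [check_noslip()] and stored on the solution.
#' @param max_condition Refuse to return a solution whose (estimated) dense
#'   condition number exceeds this; the estimate is only computed for systems
#'   small enough that the O(n^3) estimate is affordable.
#' @return An object of class `"channel_flow"`: panels, wall force densities
#'   (`density`, pN um^-2), sources, and solver metadata. Use
#'   [channel_velocity()] to evaluate the flow at interior points.
#' @seealso [top_wall_traction()], [puck_torque_from_traction()],
#'   [compute_lambda()], [closed_chamber_solution()]
#' @export
#' @examples
#' geom <- channel_geometry(1, truncation_factor = 10, panel_size = 0.25)
#' sol <- solve_channel_flow(geom, rotlet(c(0, 0, 0), c(1, 0, 0)))
#' channel_velocity(sol, c(0.5, 0.3, -0.2))
solve_channel_flow <- function(geometry, sources, caps = FALSE,
                               regularization = NULL, tol_noslip = 1e-3,
                               max_condition = 1e12) {
  stopifnot(inherits(geometry, "channel_geometry"))
  if (inherits(sources, "rotlet")) sources <- list(sources)
  if (!length(sources) || !all(vapply(sources, inherits, TRUE, "rotlet")))
    stop("`sources` must be a rotlet or list of rotlets", call. = FALSE)
  W <- geometry$half_width
  L <- geometry$length
  mu <- geometry$viscosity
  for (s in sources) {
    p <- s$position
    if (max(abs(p[2:3])) >= W)
      stop("rotlet lies on or outside the duct walls", call. = FALSE)
    if (abs(p[1]) > L / 2 - W)
      stop("rotlet lies outside the axial truncation window", call. = FALSE)
  }
  pan <- .panelize_channel(W, L, geometry$panel_size, caps = caps)
  eps <- if (is.null(regularization)) pan$hy / 2 else regularization
  check_scalar(eps, "regularization", positive = TRUE)

  u0 <- matrix(0, nrow(pan$cen), 3)
  for (s in sources) {
    if (all(s$torque == 0)) next
    u0 <- u0 + free_space_rotlet_velocity(s$torque, s$position, pan$cen, mu)
  }
  n <- nrow(pan$cen)
  if (all(u0 == 0)) {
    q <- matrix(0, n, 3)
    cond <- NA_real_
  } else {
    A <- .assemble_panel_matrix(pan, mu, eps)
    cond <- if (3 * n <= 1500) kappa(A, exact = FALSE) else NA_real_
    if (is.finite(cond) && cond > max_condition)
      stop(sprintf("panel system ill-conditioned (condition ~ %.3g)", cond),
           call. = FALSE)
    qv <- tryCatch(solve(A, -c(u0[, 1], u0[, 2], u0[, 3])),
                   error = function(e)
                     stop(sprintf("panel solve failed: %s", conditionMessage(e)),
                          call. = FALSE))
    q <- matrix(qv, n, 3)
  }
  structure(list(panels = pan, density = q, sources = sources,
                 geometry = geometry, eps = eps, mu = mu,
                 tol_noslip = tol_noslip, condition = cond),
            class = "channel_flow")
}

#' @export
print.channel_flow <- function(x, ...) {
  cat(sprintf(
    "channel flow: %d panels (%s ends), %d rotlet source(s), eps = %g um\n",
    nrow(x$panels$cen), if (x$panels$caps) "closed" else "open",
    length(x$sources), x$eps))
  if (is.finite(x$condition))
    cat(sprintf("  panel-system condition ~ %.3g\n", x$condition))
  invisible(x)
}

#' Evaluate the channel flow at interior points
#'
#' @param solution A `"channel_flow"` from [solve_channel_flow()].
#' @param points A 3-vector or n x 3 matrix of points (um).
#' @return Velocity (um/s), matching the shape of `points`.
#' @export
channel_velocity <- function(solution, points) {
  stopifnot(inherits(solution, "channel_flow"))
  one <- is.null(dim(points))
  pts <- if (one) matrix(points, 1, 3) else as.matrix(points)
  mu <- solution$mu
  u <- matrix(0, nrow(pts), 3)
  for (s in solution$sources) {
    if (all(s$torque == 0)) next
    u <- u + free_space_rotlet_velocity(s$torque, s$position, pts, mu)
  }
  w <- solution$panels$area / (8 * pi * mu)
  if (any(solution$density != 0))
    u <- u + .panel_velocity(pts, solution$panels$cen, solution$density, w,
                             solution$eps)
  if (one) drop(u) else u
}

#' No-slip residual of a channel-flow solution
#'
#' Maximum wall-collocation speed relative to the natural velocity scale
#' `|Gamma| / (8 pi mu W^2)` of the strongest source.
#'
#' @param solution A `"channel_flow"`.
#' @return List with `max_residual` (relative) and `ok` against the stored
#'   tolerance.
#' @export
check_noslip <- function(solution) {
  stopifnot(inherits(solution, "channel_flow"))
  gam <- max(c(1e-300,
               vapply(solution$sources,
                      function(s) sqrt(sum(s$torque^2)), 0)))
  scale <- gam / (8 * pi * solution$mu * solution$geometry$half_width^2)
  uw <- channel_velocity(solution, solution$panels$cen)
  rel <- max(sqrt(rowSums(uw^2))) / scale
  list(max_residual = rel, ok = rel <= solution$tol_noslip)
}

#' Closed-chamber flow via an image system
#'
#' A chamber closed by a dead-end wall is handled by mirroring every rotlet
#' through the dead-end plane: position `x -> 2 x_d - x`, and torque
#' `(Gx, Gy, Gz) -> (Gx, -Gy, -Gz)` (an axial point torque is a pseudovector,
#' so its axial component is preserved under the reflection). The combined
#' real+image system is symmetric about the plane, so the normal velocity
#' vanishes there and the plane acts as the no-slip end wall. The truncation
#' window is re-centred on the dead end so wall panels are symmetric too.
#'
#' @inheritParams solve_channel_flow
#' @param geometry A [channel_geometry()] with `dead_end` set.
#' @return A `"channel_flow"` whose `sources` include the images (flagged in
#'   `$is_image`).
#' @export
closed_chamber_solution <- function(geometry, sources, ...) {
  stopifnot(inherits(geometry, "channel_geometry"))
  xd <- geometry$dead_end
  if (is.null(xd)) stop("`geometry` has no dead end", call. = FALSE)
  if (inherits(sources, "rotlet")) sources <- list(sources)
  for (s in sources)
    if (s$position[1] > xd)
      stop("source lies beyond the dead end", call. = FALSE)
  imgs <- lapply(sources, function(s) {
    rotlet(c(2 * xd - s$position[1], s$position[2], s$position[3]),
           c(s$torque[1], -s$torque[2], -s$torque[3]))
  })
  geo2 <- geometry
  geo2$dead_end <- NULL
  # re-centre truncation on the dead-end plane
  pan_shift <- xd
  all_src <- c(sources, imgs)
  shifted <- lapply(all_src, function(s)
    rotlet(s$position - c(pan_shift, 0, 0), s$torque))
  sol <- solve_channel_flow(geo2, shifted, ...)
  # shift panel frame back to lab coordinates
  sol$panels$cen[, 1] <- sol$panels$cen[, 1] + pan_shift
  sol$panels$x0 <- pan_shift
  sol$sources <- lapply(sol$sources, function(s)
    rotlet(s$position + c(pan_shift, 0, 0), s$torque))
  sol$is_image <- rep(c(FALSE, TRUE), c(length(sources), length(imgs)))
  sol$dead_end <- xd
  sol
}
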