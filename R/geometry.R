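#' Point torque (rotlet) singularity
#'
#' A rotlet is the fundamental point-torque solution of Stokes flow. A swimming
#' bacterium aligned with the channel axis is idealized as two equal and
#' opposite axial rotlets (+Gamma_M and -Gamma_M along x) separated by the
#' dipole length.
#'
#' @param position Numeric length-3, the rotlet location (um).
#' @param torque Numeric length-3, the point torque (pN um). May be zero for
#'   null/test cases.
#' @return An object of class `"rotlet"`.
#' @export
#' @examples
#' rotlet(c(0, 0, 0), c(1, 0, 0))
rotlet <- function(position, torque) {
  if (!is.numeric(position) || length(position) != 3 || !all(is.finite(position)))
    stop("`position` must be a finite numeric 3-vector", call. = FALSE)
  if (!is.numeric(torque) || length(torque) != 3 || !all(is.finite(torque)))
    stop("`torque` must be a finite numeric 3-vector", call. = FALSE)
  structure(list(position = as.numeric(position), torque = as.numeric(torque)),
            class = "rotlet")
}

#' @export
print.rotlet <- function(x, ...) {
  cat(sprintf("rotlet at (%g, %g, %g) um, torque (%g, %g, %g) pN um\n",
              x$position[1], x$position[2], x$position[3],
              x$torque[1], x$torque[2], x$torque[3]))
  invisible(x)
}

#' Square-channel geometry for the boundary-element solver
#'
#' The channel is a square duct of half-width `half_width` (cross-section
#' `2W x 2W`), axis along x, bottom wall at z = -W fixed to the substrate and
#' top wall at z = +W belonging to the puck. The "infinite" channel is realized
#' by truncating at `truncation_factor * half_width` with open ends; axial
#' screening in a duct is exponential, so the truncation error is negligible
#' for the default factor.
#'
#' @param half_width Channel half-width W (um).
#' @param truncation_factor Truncated length as a multiple of W (default 40).
#' @param panel_size Target panel edge h (um); must satisfy `h <= W/4`.
#'   Default `half_width / 4`.
#' @param dead_end Optional axial coordinate of a closed end wall (um), for
#'   closed chambers. Must lie inside the truncation window.
#' @param viscosity Dynamic viscosity mu (pN s um^-2), default water.
#' @return An object of class `"channel_geometry"`.
#' @export
#' @examples
#' channel_geometry(1, truncation_factor = 12)
channel_geometry <- function(half_width,
                             truncation_factor = 40,
                             panel_size = half_width / 4,
                             dead_end = NULL,
                             viscosity = tp_constants$water_viscosity_pN_s_per_um2) {
  check_scalar(half_width, "half_width", positive = TRUE)
  check_scalar(truncation_factor, "truncation_factor", positive = TRUE)
  check_scalar(panel_size, "panel_size", positive = TRUE)
  check_scalar(viscosity, "viscosity", positive = TRUE)
  W <- half_width
  L <- truncation_factor * W
  if (L < 10 * W)
    stop("truncation length must be at least 10 half-widths", call. = FALSE)
  if (panel_size > W / 4 + 1e-12)
    stop("`panel_size` must be <= half_width / 4", call. = FALSE)
  if (!is.null(dead_end)) {
    check_scalar(dead_end, "dead_end")
    if (abs(dead_end) > L / 2)
      stop("`dead_end` must lie within the truncation window", call. = FALSE)
  }
  structure(list(half_width = W, length = L, panel_size = panel_size,
                 dead_end = dead_end, viscosity = viscosity),
            class = "channel_geometry")
}

#' @export
print.channel_geometry <- function(x, ...) {
  cat(sprintf(
    "square channel: half-width %g um, truncated length %g um, panel %g um\n",
    x$half_width, x$length, x$panel_size))
  if (!is.null(x$dead_end))
    cat(sprintf("  dead end at x = %g um\n", x$dead_end))
  cat(sprintf("  viscosity %g pN s/um^2\n", x$viscosity))
  invisible(x)
}
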