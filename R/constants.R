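#' Physical constants in package units
#'
#' The package works in micrometres, seconds and piconewtons, so energies are
#' pN um and the Boltzmann constant is the exact SI value converted once:
#' 1.380649e-23 J/K = 1.380649e-5 pN um / K.
#'
#' @format A named list with elements:
#' \describe{
#'   \item{kB_pN_um_per_K}{Boltzmann constant, pN um K^-1.}
#'   \item{water_viscosity_pN_s_per_um2}{Dynamic viscosity of water at room
#'     temperature, pN s um^-2 (equal to 1e-3 Pa s).}
#'   \item{room_temperature_K}{Default temperature, 298.15 K.}
#' }
#' @export
#' @examples
#' tp_constants$kB_pN_um_per_K * tp_constants$room_temperature_K  # ~4.1e-3 pN um
tp_constants <- list(
  kB_pN_um_per_K = 1.380649e-5,
  water_viscosity_pN_s_per_um2 = 1e-3,
  room_temperature_K = 298.15
)

#' Evaluate a function with a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so that seeded simulations do not disturb
#' the caller's RNG stream. `seed = NULL` leaves the global stream untouched.
#'
#' @param seed Integer seed or `NULL`.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# internal argument checkers --------------------------------------------------

check_scalar <- function(x, name, positive = FALSE, nonneg = FALSE,
                         finite = TRUE) {
  if (!is.numeric(x) || length(x) != 1 || (finite && !is.finite(x)))
    stop(sprintf("`%s` must be a finite numeric scalar", name), call. = FALSE)
  if (positive && x <= 0)
    stop(sprintf("`%s` must be > 0", name), call. = FALSE)
  if (nonneg && x < 0)
    stop(sprintf("`%s` must be >= 0", name), call. = FALSE)
  invisible(x)
}
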