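# Formats, configuration and the pipeline driver. CSV for tables, YAML for
# configuration, JSON for results. Angles are stored unwrapped (cumulative,
# not mod 2 pi) since crossings and chamber runs accumulate many radians.

#' Read a trajectory table
#'
#' Accepts the package's trajectory CSV layout: required columns `t_s` and
#' `theta_rad`, optional `xb_um` (any column order). Units are enforced by the
#' column-name suffixes (`_s`, `_um`, `_rad`).
#'
#' @param path CSV file path.
#' @return A `"crossing_trajectory"` data frame if `xb_um` is present,
#'   otherwise an `"angle_series"` data frame.
#' @export
read_trajectory <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path), call. = FALSE)
  df <- read.csv(path, check.names = TRUE)
  need <- c("t_s", "theta_rad")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop(sprintf("missing required column(s): %s", paste(miss, collapse = ", ")),
         call. = FALSE)
  for (cn in intersect(c("t_s", "xb_um", "theta_rad"), names(df))) {
    if (!is.numeric(df[[cn]]) || anyNA(df[[cn]]))
      stop(sprintf("column `%s` must be numeric without NAs", cn), call. = FALSE)
  }
  if (is.unsorted(df$t_s, strictly = TRUE))
    stop("`t_s` must be strictly increasing", call. = FALSE)
  ord <- c(intersect(c("t_s", "xb_um", "theta_rad"), names(df)),
           setdiff(names(df), c("t_s", "xb_um", "theta_rad")))
  df <- df[ord]
  meta_path <- paste0(path, ".json")
  if (file.exists(meta_path))
    attr(df, "metadata") <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  cls <- if ("xb_um" %in% names(df)) "crossing_trajectory" else "angle_series"
  class(df) <- c(cls, "data.frame")
  df
}

#' Write a trajectory table (with JSON metadata sidecar)
#'
#' @param trajectory Data frame with `t_s`, `theta_rad` and optionally
#'   `xb_um`.
#' @param path Output CSV path; metadata (seed, parameters) goes to
#'   `<path>.json`.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(trajectory, path) {
  keep <- intersect(c("t_s", "xb_um", "theta_rad"), names(trajectory))
  df <- as.data.frame(trajectory)[keep]
  # full-precision text so that read_trajectory() round-trips exactly
  df[] <- lapply(df, function(x) formatC(x, digits = 17, format = "g"))
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  meta <- list(seed = attr(trajectory, "seed"),
               dt = attr(trajectory, "dt"),
               W = attr(trajectory, "W"),
               lambda = attr(trajectory, "lambda"),
               noise = attr(trajectory, "noise"))
  b <- attr(trajectory, "bacterium")
  if (!is.null(b)) meta$bacterium <- unclass(b)
  p <- attr(trajectory, "puck")
  if (!is.null(p)) meta$puck <- unclass(p)
  jsonlite::write_json(meta[!vapply(meta, is.null, TRUE)],
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

# configuration ----------------------------------------------------------------

.default_config <- function() {
  list(
    seed = 1L,
    channel = list(half_width_um = 1, truncation_factor = 20,
                   panel_size_um = 0.25,
                   viscosity_pN_s_per_um2 = 1e-3, dead_end_um = NULL),
    bacterium = list(motor_torque_pN_um = 2, body_length_um = 5, alpha = 1.5,
                     swim_speed_um_s = 20),
    puck = list(radius_um = 10, diffusivity_rad2_s = 6e-5,
                temperature_K = 298.15),
    bath = list(concentration_per_ml = 6e8, curvature_radius_um = 50,
                body_length_um = 3, force_pN = 0.2,
                collision_rate_per_perimeter = 0.06, contact_time_s = 0.3,
                rectification_c = 1.5),
    simulation = list(dt_s = 0.1, duration_s = 600,
                      angle_noise_rad = 0.01, position_noise_um = 0.2),
    inference = list(lambda = NULL, reversal_bandwidth_um = 1,
                     prereversal_fraction = 0.9)
  )
}

#' Read (and validate) a run configuration
#'
#' YAML configuration with sections `channel`, `bacterium`, `puck`, `bath`,
#' `simulation`, `inference` and a global `seed`. Missing entries fall back to
#' package defaults; unknown sections or non-numeric physical entries are
#' schema errors raised before any computation. Physical quantities carry
#' their units in the key names.
#'
#' @param path YAML file path, or `NULL` for the package defaults.
#' @return A validated `"run_config"` list with a `config_hash` attribute.
#' @export
#' @examples
#' cfg <- read_run_config()  # defaults
#' cfg$puck$radius_um
read_run_config <- function(path = NULL) {
  cfg <- .default_config()
  if (!is.null(path)) {
    if (!file.exists(path)) stop(sprintf("no such config: %s", path),
                                 call. = FALSE)
    user <- yaml::read_yaml(path)
    bad <- setdiff(names(user), c(names(cfg)))
    if (length(bad))
      stop(sprintf("unknown config section(s): %s", paste(bad, collapse = ", ")),
           call. = FALSE)
    for (s in names(user)) {
      if (is.list(cfg[[s]]) && is.list(user[[s]])) {
        unknown <- setdiff(names(user[[s]]), names(cfg[[s]]))
        if (length(unknown))
          stop(sprintf("unknown key(s) in `%s`: %s", s,
                       paste(unknown, collapse = ", ")), call. = FALSE)
        cfg[[s]] <- modifyList(cfg[[s]], user[[s]])
      } else cfg[[s]] <- user[[s]]
    }
  }
  .validate_config(cfg)
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  yaml::write_yaml(cfg, tmp)
  attr(cfg, "config_hash") <- unname(tools::md5sum(tmp))
  class(cfg) <- "run_config"
  cfg
}

.validate_config <- function(cfg) {
  pos <- function(sec, key) {
    v <- cfg[[sec]][[key]]
    if (is.null(v)) return(invisible())
    if (!is.numeric(v) || length(v) != 1 || !is.finite(v) || v <= 0)
      stop(sprintf("config %s.%s must be a positive number", sec, key),
           call. = FALSE)
  }
  for (k in names(.default_config()$channel)) if (k != "dead_end_um") pos("channel", k)
  for (k in names(.default_config()$bacterium)) pos("bacterium", k)
  for (k in names(.default_config()$puck)) pos("puck", k)
  for (k in setdiff(names(.default_config()$bath), "rectification_c")) pos("bath", k)
  pos("simulation", "dt_s"); pos("simulation", "duration_s")
  if (!is.numeric(cfg$seed) || length(cfg$seed) != 1)
    stop("config `seed` must be a single integer", call. = FALSE)
  invisible(cfg)
}

.cfg_bacterium <- function(cfg)
  torque_dipole_spec(cfg$bacterium$motor_torque_pN_um,
                     cfg$bacterium$body_length_um,
                     cfg$bacterium$alpha, cfg$bacterium$swim_speed_um_s)

.cfg_puck <- function(cfg)
  puck_state(cfg$puck$radius_um, diffusivity = cfg$puck$diffusivity_rad2_s,
             temperature = cfg$puck$temperature_K)

.cfg_geometry <- function(cfg)
  channel_geometry(cfg$channel$half_width_um, cfg$channel$truncation_factor,
                   cfg$channel$panel_size_um, cfg$channel$dead_end_um,
                   cfg$channel$viscosity_pN_s_per_um2)

.cfg_bath <- function(cfg)
  bath_params(cfg$bath$concentration_per_ml, cfg$bath$curvature_radius_um,
              cfg$bath$body_length_um, cfg$bath$force_pN,
              cfg$bath$collision_rate_per_perimeter, cfg$bath$contact_time_s,
              cfg$bath$rectification_c)

#' Run a pipeline command from a configuration
#'
#' Deterministic given (config, seed). Commands:
#' \describe{
#'   \item{`lambda`}{[compute_lambda()] on the configured channel; the result
#'     is cached in the session and reused by `profile`.}
#'   \item{`profile`}{analytic crossing profile on an `X_B` grid (uses the
#'     cached or configured lambda).}
#'   \item{`simulate-crossing`}{one noisy crossing trajectory.}
#'   \item{`simulate-bath`}{chiral-bath angle traces for the configured disc.}
#'   \item{`simulate-chamber`}{chamber-occupancy event series.}
#'   \item{`estimate`}{rate and diffusivity estimates for a trajectory read
#'     from `input`.}
#'   \item{`fit-alpha`}{dipole-ratio fit over trajectories read from the CSV
#'     paths in `input`.}
#'   \item{`collapse`}{collapse of the trajectories in `input` onto a common
#'     grid.}
#' }
#'
#' @param config A `"run_config"` from [read_run_config()] (or a path).
#' @param command One of the commands above.
#' @param input Optional input path(s) for `estimate` / `fit-alpha` /
#'   `collapse`.
#' @param seed Overrides the config seed when non-NULL.
#' @return A `"result_envelope"`: list with `payload`, `command`,
#'   `config_hash`, `package_version`, `timestamp`, `seed`.
#' @export
run_pipeline <- function(config = read_run_config(), command, input = NULL,
                         seed = NULL) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  command <- match.arg(command, c("lambda", "profile", "simulate-crossing",
                                  "simulate-bath", "simulate-chamber",
                                  "estimate", "fit-alpha", "collapse"))
  seed <- if (is.null(seed)) config$seed else seed
  lam_cfg <- config$inference$lambda
  get_lambda <- function() {
    if (!is.null(lam_cfg)) return(list(value = lam_cfg, source = "config"))
    key <- paste0("lambda|", attr(config, "config_hash"))
    hit <- .tp_cache[[key]]
    if (!is.null(hit)) return(list(value = hit, source = "cached"))
    lr <- compute_lambda(.cfg_geometry(config),
                         refinement_levels = config$channel$panel_size_um * c(1, 2 / 3))
    assign(key, lr$value, envir = .tp_cache)
    list(value = lr$value, source = "computed")
  }
  payload <- switch(
    command,
    "lambda" = {
      lr <- compute_lambda(.cfg_geometry(config),
                           refinement_levels = config$channel$panel_size_um * c(1, 2 / 3))
      assign(paste0("lambda|", attr(config, "config_hash")), lr$value,
             envir = .tp_cache)
      list(lambda = lr$value, uncertainty = lr$uncertainty,
           levels = lr$levels)
    },
    "profile" = {
      lam <- get_lambda()
      b <- .cfg_bacterium(config); p <- .cfg_puck(config)
      xb <- seq(0, 2 * p$radius + b$dipole_length, length.out = 256)
      data.frame(xb_um = xb,
                 dtheta_rad = crossing_profile(b, p, config$channel$half_width_um,
                                               lam$value, xb),
                 regime = ifelse(xb <= 2 * p$radius - b$body_length,
                                 "dipole", "single"),
                 lambda_source = lam$source)
    },
    "simulate-crossing" = {
      b <- .cfg_bacterium(config); p <- .cfg_puck(config)
      lam <- get_lambda()
      generate_crossing(b, p, config$channel$half_width_um, lam$value,
                        noise = list(D_theta = p$diffusivity,
                                     angle_sd = config$simulation$angle_noise_rad,
                                     position_sd = config$simulation$position_noise_um),
                        dt = config$simulation$dt_s, seed = seed)
    },
    "simulate-bath" = {
      p <- .cfg_puck(config)
      simulate_bath(.cfg_bath(config), p$radius,
                    duration = config$simulation$duration_s,
                    dt = config$simulation$dt_s, seed = seed)
    },
    "simulate-chamber" = {
      p <- .cfg_puck(config)
      lam <- get_lambda()
      generate_occupancy_series(chamber_layout(), puck = p,
                                W = config$channel$half_width_um,
                                lambda = lam$value,
                                dipole_ratio = config$bacterium$alpha,
                                motor_torque = config$bacterium$motor_torque_pN_um,
                                duration = config$simulation$duration_s,
                                dt = config$simulation$dt_s, seed = seed)
    },
    "estimate" = {
      if (is.null(input)) stop("`estimate` needs an input path", call. = FALSE)
      tr <- read_trajectory(input)
      list(rate = unclass(estimate_rate(tr)),
           diffusivity = unclass(estimate_diffusivity(tr))[c("D", "se")])
    },
    "fit-alpha" = {
      if (is.null(input)) stop("`fit-alpha` needs input paths", call. = FALSE)
      trs <- lapply(input, read_trajectory)
      lam <- get_lambda()
      b <- .cfg_bacterium(config); p <- .cfg_puck(config)
      fit <- fit_alpha(trs, known = list(
        lambda = lam$value, W = config$channel$half_width_um,
        motor_torque = b$motor_torque, mobility = p$mobility,
        swim_speed = b$swim_speed, body_length = b$body_length,
        radius = p$radius),
        prereversal_fraction = config$inference$prereversal_fraction)
      list(alpha = fit$alpha, se = fit$se, ci95 = unname(confint(fit)))
    },
    "collapse" = {
      if (is.null(input)) stop("`collapse` needs input paths", call. = FALSE)
      trs <- lapply(input, read_trajectory)
      as.data.frame(collapse_crossings(trs))
    })
  structure(list(payload = payload, command = command,
                 config_hash = attr(config, "config_hash"),
                 package_version = as.character(utils::packageVersion("torquepuck")),
                 timestamp = format(Sys.time(), tz = "UTC"),
                 seed = seed),
            class = "result_envelope")
}

#' @export
print.result_envelope <- function(x, ...) {
  cat(sprintf("result envelope: command `%s`, seed %s, config %s\n",
              x$command, x$seed, substr(x$config_hash, 1, 8)))
  utils::str(x$payload, max.level = 1, give.attr = FALSE)
  invisible(x)
}

#' Write a result envelope to JSON
#'
#' @param envelope A `"result_envelope"`.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_result <- function(envelope, path) {
  stopifnot(inherits(envelope, "result_envelope"))
  jsonlite::write_json(envelope, path, auto_unbox = TRUE, digits = NA,
                       force = TRUE, pretty = TRUE)
  invisible(path)
}
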