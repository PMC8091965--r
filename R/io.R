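#' @title Trial and configuration I/O
#' @description
#' Plain-text persistence: time-series CSV with unit-suffixed channel
#' names plus a JSON sidecar for metadata (sampling rate, body mass,
#' heel-strike events, configuration hash), and YAML/JSON run
#' configuration with strict key validation. SI units are used
#' internally; unit suffixes in CSV headers are authoritative and
#' converted at the boundary (`angle_deg` to radians, `k_see` N/mm to
#' N/m).
#' @name cli_io
NULL

.sidecar_path <- function(path) paste0(path, ".json")

#' Write a gait trial to CSV (+ JSON sidecar)
#'
#' Values go to a CSV with unit-suffixed headers (`time_s`, `angle_rad`,
#' `omega_rad_s`, ...) at full float precision; events and scalar
#' metadata go to `<path>.json`. The round trip through [read_trial()]
#' reproduces the numeric values exactly.
#'
#' @param trial A `gait_trial`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_trial <- function(trial, path) {
  out <- as.data.frame(trial)
  nm <- names(out)
  nm[nm == "time"] <- "time_s"
  nm[nm == "angle"] <- "angle_rad"
  nm[nm == "omega"] <- "omega_rad_s"
  names(out) <- nm
  utils::write.csv(format(out, digits = 17, trim = TRUE, scientific = FALSE),
                   path, row.names = FALSE, quote = FALSE)
  meta <- list(
    sample_rate = attr(trial, "sample_rate"),
    body_mass = attr(trial, "body_mass"),
    stance_fraction = attr(trial, "stance_fraction"),
    heel_strike = as.integer(heel_strikes(trial)),
    config_hash = rlang::hash(attr(trial, "spec"))
  )
  jsonlite::write_json(meta, .sidecar_path(path), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a gait trial from CSV (+ JSON sidecar)
#'
#' Parses a unit-suffixed time-series CSV: the time column must be
#' strictly increasing and uniform (violations raise an error naming the
#' offending row); degree-suffixed angle/velocity channels are converted
#' to radians. Metadata is taken from the `<path>.json` sidecar when
#' present.
#'
#' @param path CSV path written by [write_trial()] or hand-built to the
#'   same dialect.
#' @return A `gait_trial` tibble.
#' @export
read_trial <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  raw <- utils::read.csv(path, check.names = FALSE)
  if (!all(vapply(raw, is.numeric, logical(1)))) {
    stop("all cells must be numeric")
  }
  nm <- names(raw)
  tcol <- which(nm %in% c("time_s", "time"))
  if (length(tcol) != 1) stop("missing required channel time_s")
  time <- raw[[tcol]]
  dtv <- diff(time)
  bad <- which(dtv <= 0)
  if (length(bad) > 0) {
    stop(sprintf("time must be strictly increasing: violation at row %d",
                 bad[1] + 1))
  }
  if (max(dtv) - min(dtv) > 1e-9) {
    stop(sprintf("time base not uniform: irregular step at row %d",
                 which.max(abs(dtv - dtv[1])) + 1))
  }
  out <- tibble::tibble(time = time)
  for (j in seq_along(nm)) {
    if (j == tcol) next
    cn <- nm[j]; v <- raw[[j]]
    if (cn %in% c("angle_deg")) {
      out$angle <- v * pi / 180
    } else if (cn %in% c("angle_rad", "angle")) {
      out$angle <- v
    } else if (cn %in% c("omega_deg_s")) {
      out$omega <- v * pi / 180
    } else if (cn %in% c("omega_rad_s", "omega")) {
      out$omega <- v
    } else {
      out[[sub("_(mV|ml_s)$", "", cn)]] <- v
    }
  }
  if (!"angle" %in% names(out)) stop("missing required channel angle_rad")
  if (!"omega" %in% names(out)) {
    dt <- time[2] - time[1]
    n <- nrow(out)
    om <- numeric(n)
    om[2:(n - 1)] <- (out$angle[3:n] - out$angle[1:(n - 2)]) / (2 * dt)
    om[1] <- (out$angle[2] - out$angle[1]) / dt
    om[n] <- (out$angle[n] - out$angle[n - 1]) / dt
    out$omega <- om
  }
  sp <- .sidecar_path(path)
  if (file.exists(sp)) {
    meta <- jsonlite::read_json(sp, simplifyVector = TRUE)
    attr(out, "heel_strike") <- as.integer(meta$heel_strike)
    attr(out, "body_mass") <- meta$body_mass
    attr(out, "sample_rate") <- meta$sample_rate
    attr(out, "stance_fraction") <- meta$stance_fraction
    attr(out, "config_hash") <- meta$config_hash
  } else {
    attr(out, "heel_strike") <- integer(0)
    attr(out, "sample_rate") <- 1 / (time[2] - time[1])
  }
  class(out) <- c("gait_trial", class(out))
  out
}

.config_schema <- list(
  muscle = c("f_max", "l_opt", "v_max", "k_see", "l_slack", "eps_ref",
             "w", "c_fl", "k_fv", "n_fv", "k_pass", "tau_act"),
  geometry = c("r0", "theta_ref", "l_mtu_ref", "constant_arm"),
  reflex = c("gain", "delay", "prestim", "psi", "norm_by_activation"),
  gait = c("stride_time", "stance_fraction", "sample_rate", "harmonics",
           "noise_sd", "body_mass", "n_strides"),
  simulation = c("dt", "mode", "alpha", "lpf_cutoff", "max_iters", "tol",
                 "n_strides", "discard"),
  metrics = c("n_strides", "discard", "window", "hp", "lp"),
  stats = c("alpha", "gg", "exclude_subjects"),
  seed = NULL
)

#' Read and validate a run configuration (YAML or JSON)
#'
#' Flat, sectioned key-value configuration in SI units (`k_see` is
#' accepted in N/mm as in [mtu_params()]). Unknown sections or keys are
#' rejected with the offending name.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A validated named list of class `run_config`.
#' @export
read_config <- function(path) {
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  validate_config(cfg)
}

#' @rdname read_config
#' @param cfg A configuration list to validate.
#' @export
validate_config <- function(cfg) {
  bad <- setdiff(names(cfg), names(.config_schema))
  if (length(bad) > 0) stop("unknown config section: ", bad[1])
  for (sec in names(cfg)) {
    allowed <- .config_schema[[sec]]
    if (is.null(allowed)) next
    badk <- setdiff(names(cfg[[sec]]), allowed)
    if (length(badk) > 0) {
      stop(sprintf("unknown key '%s' in config section '%s'", badk[1], sec))
    }
  }
  structure(cfg, class = c("run_config", "list"))
}

#' Materialize parameter objects from a run configuration
#'
#' @param cfg A `run_config` from [read_config()].
#' @return A list with `p` ([mtu_params()]), `geom` ([ankle_geometry()]),
#'   `rp` ([reflex_params()]), `spec` ([gait_spec()]) built from the
#'   corresponding config sections (package defaults fill the gaps).
#' @export
config_objects <- function(cfg) {
  cfg <- validate_config(unclass(cfg))
  p <- do.call(mtu_params, as.list(cfg$muscle %||% list()))
  geom_args <- as.list(cfg$geometry %||% list())
  geom_args$p <- p
  geom <- do.call(ankle_geometry, geom_args)
  rp <- do.call(reflex_params, as.list(cfg$reflex %||% list()))
  gait_args <- as.list(cfg$gait %||% list())
  gait_args$n_strides <- NULL
  spec <- do.call(gait_spec, gait_args)
  list(p = p, geom = geom, rp = rp, spec = spec)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
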