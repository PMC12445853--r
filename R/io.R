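## Configuration loading, scenario presets and tabular export.

#' Environments of a named perturbation scenario
#'
#' The two in-built proof-of-concept scenarios: an instantaneous doubling of
#' ambient CO2 (400 to 800 ppm) or of vapour pressure deficit (1 to 2 kPa),
#' both starting from typical unstressed temperate growth conditions
#' (25 degC, 800 umol m-2 s-1 light, standard pressure).
#'
#' @param scenario \code{"co2_doubling"} or \code{"vpd_doubling"}.
#' @return A list with elements \code{env0} and \code{env1}.
#' @examples
#' scenario_environments("co2_doubling")$env1$ca_ppm  # 800
#' @export
scenario_environments <- function(scenario = c("co2_doubling", "vpd_doubling")) {
  scenario <- match.arg(scenario)
  base <- environment_state(temp_c = 25, vpd = 1000, ca_ppm = 400,
                            ppfd = 800, patm = 101325)
  env1 <- switch(scenario,
    co2_doubling = environment_state(temp_c = 25, vpd = 1000, ca_ppm = 800,
                                     ppfd = 800, patm = 101325),
    vpd_doubling = environment_state(temp_c = 25, vpd = 2000, ca_ppm = 400,
                                     ppfd = 800, patm = 101325))
  list(env0 = base, env1 = env1)
}

config_error <- function(msg) {
  stop(structure(class = c("leaflapse_config_error", "error", "condition"),
                 list(message = msg, call = NULL)))
}

#' Read and validate a run configuration
#'
#' A run configuration is a YAML file with fields
#' \code{scenario} (\code{co2_doubling}, \code{vpd_doubling} or
#' \code{custom}), optional \code{env0}/\code{env1} blocks (required for --
#' and only allowed with -- \code{custom}), an optional \code{constants}
#' block of [photo_constants()] overrides, and optional
#' \code{jmax_acclimate}, \code{clip_gs}, \code{report_precision} and
#' \code{seed} entries (the engine is deterministic; \code{seed} is
#' reserved).
#'
#' @param path Path to a YAML configuration file.
#' @return A validated list of class \code{leaflapse_config} with resolved
#'   \code{env0}, \code{env1} and \code{constants}.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) config_error(paste0("config file not found: ", path))
  raw <- tryCatch(yaml::read_yaml(path),
                  error = function(e) config_error(paste0("cannot parse YAML: ",
                                                          conditionMessage(e))))
  if (!is.list(raw)) config_error("config must be a YAML mapping")
  known <- c("scenario", "env0", "env1", "constants", "jmax_acclimate",
             "clip_gs", "report_precision", "seed", "output_dir")
  unknown <- setdiff(names(raw), known)
  if (length(unknown))
    config_error(paste0("unknown config field(s): ",
                        paste(unknown, collapse = ", ")))
  scen <- raw$scenario
  if (is.null(scen) || !is.character(scen) || length(scen) != 1L ||
      !scen %in% c("co2_doubling", "vpd_doubling", "custom"))
    config_error("scenario must be one of co2_doubling, vpd_doubling, custom")
  if (scen == "custom") {
    if (is.null(raw$env0) || is.null(raw$env1))
      config_error("custom scenario requires explicit env0 and env1 blocks")
    envs <- list(
      env0 = tryCatch(do.call(environment_state, raw$env0),
                      error = function(e) config_error(paste0("env0: ", conditionMessage(e)))),
      env1 = tryCatch(do.call(environment_state, raw$env1),
                      error = function(e) config_error(paste0("env1: ", conditionMessage(e)))))
  } else {
    if (!is.null(raw$env0) || !is.null(raw$env1))
      config_error("named scenarios forbid explicit env0/env1 blocks")
    envs <- scenario_environments(scen)
  }
  constants <- tryCatch(do.call(photo_constants, as.list(raw$constants)),
                        error = function(e) config_error(paste0("constants: ",
                                                                conditionMessage(e))))
  cfg <- list(scenario = scen, env0 = envs$env0, env1 = envs$env1,
              constants = constants,
              jmax_acclimate = isTRUE(raw$jmax_acclimate),
              clip_gs = if (is.null(raw$clip_gs)) TRUE else isTRUE(raw$clip_gs),
              report_precision = if (is.null(raw$report_precision)) 4L
                                 else as.integer(raw$report_precision),
              seed = raw$seed, output_dir = raw$output_dir)
  class(cfg) <- "leaflapse_config"
  cfg
}

#' Write a time-lapse table to CSV
#'
#' One row per step and trait, with columns scenario, step_index,
#' step_label, timescale, trait, value and (if present) normalized_value.
#' Output is deterministic: identical configurations give byte-identical
#' files.
#'
#' @param timelapse A \code{leaf_timelapse}.
#' @param path Output CSV path.
#' @return \code{path}, invisibly.
#' @export
write_timelapse <- function(timelapse, path) {
  stopifnot(inherits(timelapse, "leaf_timelapse"))
  utils::write.csv(timelapse$table, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Run a configured scenario and write its outputs
#'
#' Executes [run_scenario()] for the configuration, normalizes the
#' time-lapse, and writes \code{timelapse.csv}, \code{percent_changes.csv}
#' and a \code{metadata.yaml} sidecar (echoing every physiological constant
#' so deviations from defaults are auditable) into the output directory.
#'
#' @param config A path to a YAML config or a \code{leaflapse_config}.
#' @param output_dir Output directory (created if missing); defaults to the
#'   config's \code{output_dir} or the working directory.
#' @param quiet Suppress per-step log lines.
#' @return Invisibly, a list with the \code{leaf_timelapse} and the written
#'   file paths.
#' @export
run_from_config <- function(config, output_dir = NULL, quiet = FALSE) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "leaflapse_config"))
  if (is.null(output_dir)) output_dir <- config$output_dir
  if (is.null(output_dir)) output_dir <- "."
  if (!dir.exists(output_dir)) dir.create(output_dir, recursive = TRUE)

  tl <- run_scenario(config$env0, config$env1, config$constants,
                     jmax_acclimate = config$jmax_acclimate,
                     clip_gs = config$clip_gs, scenario = config$scenario)
  tl <- normalize_timelapse(tl)
  if (!quiet) {
    for (i in seq_along(tl$steps)) {
      st <- tl$steps[[i]]
      message(sprintf(
        "step %d (%s): ci=%.6g Pa gs=%.6g vcmax=%.6g a_leaf=%.6g ratio_ci=%.6g ratio_gs=%.6g",
        i - 1L, STEP_LABELS[i], st$ci, st$gs, st$vcmax, st$a_leaf,
        st$ratio_ci, st$ratio_gs))
    }
  }
  paths <- list(
    timelapse = file.path(output_dir, "timelapse.csv"),
    percent_changes = file.path(output_dir, "percent_changes.csv"),
    metadata = file.path(output_dir, "metadata.yaml"))
  write_timelapse(tl, paths$timelapse)
  utils::write.csv(percent_changes(tl), paths$percent_changes,
                   row.names = FALSE, quote = FALSE)
  yaml::write_yaml(list(scenario = config$scenario,
                        env0 = unclass(config$env0),
                        env1 = unclass(config$env1),
                        constants = unclass(config$constants),
                        jmax_acclimate = config$jmax_acclimate,
                        clip_gs = config$clip_gs,
                        functional_control_exceeded =
                          tl$functional_control_exceeded),
                   paths$metadata)
  invisible(list(timelapse = tl, paths = paths))
}

#' Optimal chi and its ingredients for one environment
#'
#' Convenience report used by the command-line interface: chi together with
#' xi, GammaStar and K, each with units.
#'
#' @param temp_c,vpd,ca_ppm,patm Environment (VPD in Pa).
#' @param constants A [photo_constants()] object.
#' @return A data frame with quantity, value, units.
#' @export
chi_report <- function(temp_c = 25, vpd = 1000, ca_ppm = 400, patm = 101325,
                       constants = photo_constants()) {
  env <- environment_state(temp_c = temp_c, vpd = vpd, ca_ppm = ca_ppm,
                           ppfd = 1, patm = patm)
  co <- chi_optimal(env, constants)
  data.frame(
    quantity = c("chi", "xi", "gamma_star", "big_k", "ci_acclim"),
    value = c(co$chi, co$xi, co$gamma_star, co$big_k, co$ci_acclim),
    units = c("-", "Pa^0.5", "Pa", "Pa", "Pa"),
    stringsAsFactors = FALSE)
}
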