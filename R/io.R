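# Configuration loading/validation, result containers and writers.
# Snapshots and observation sets use R's native serialization (RDS) as the
# self-describing runtime container; diagnostics go to CSV, manifests to
# canonical JSON, and field snapshots can additionally be exported as ASCII
# VTK rectilinear-grid files for visualization.

config_schema <- list(
  case = c("name", "type", "scale"),
  grid = c("extent", "cells", "wall_y", "origin"),
  solver = c("nu", "re", "u_ref", "l_ref", "dt", "cfl", "bulk_u",
             "div_tol"),
  schedule = c("T", "n_phi", "t_phi", "dtau"),
  da = c("D", "sampling", "seed", "reproject", "pulses"),
  observation = c("window", "dw", "spin_up", "obs_pulses"))

#' Load and validate a case configuration
#'
#' Reads a YAML case file, rejects unknown sections/keys, applies defaults
#' and returns the materialized configuration (which [save_config()] can
#' round-trip).
#'
#' @param path YAML file path.
#' @return validated configuration list of class `flow_config`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- yaml::read_yaml(path)
  validate_config(raw)
}

#' @rdname load_config
#' @param config a configuration list (as from YAML).
#' @export
validate_config <- function(config) {
  unknown <- setdiff(names(config), names(config_schema))
  if (length(unknown))
    stop("unknown config section(s): ", paste(unknown, collapse = ", "))
  for (sec in names(config)) {
    bad <- setdiff(names(config[[sec]]), config_schema[[sec]])
    if (length(bad))
      stop(sprintf("unknown key(s) in '%s': %s", sec,
                   paste(bad, collapse = ", ")))
  }
  defaults <- list(
    case = list(name = "custom", type = "custom", scale = "reduced"),
    grid = list(extent = c(1, 1, 1), cells = c(16, 16, 1), wall_y = TRUE,
                origin = c(0, 0, 0)),
    solver = list(nu = NULL, re = 100, u_ref = 1, l_ref = 1, dt = NA,
                  cfl = 0.4, bulk_u = NA, div_tol = 1e-8),
    schedule = list(T = 1, n_phi = 1, t_phi = NULL, dtau = NULL),
    da = list(D = 10, sampling = "cycle", seed = 1, reproject = TRUE,
              pulses = 10),
    observation = list(window = "full", dw = 1, spin_up = 0,
                       obs_pulses = 10))
  out <- defaults
  for (sec in names(config))
    out[[sec]] <- utils::modifyList(defaults[[sec]], config[[sec]],
                                    keep.null = TRUE)
  so <- out$solver
  nu <- if (!is.null(so$nu)) so$nu else so$u_ref * so$l_ref / so$re
  if (nu <= 0) stop("viscosity must be positive (nu = ", nu, ")")
  if (!is.na(so$dt) && so$dt <= 0) stop("dt must be positive")
  if (out$da$D < 0) stop("D must be non-negative")
  structure(out, class = "flow_config")
}

#' @rdname load_config
#' @export
save_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

# Deterministic digest of a configuration (canonical JSON -> md5).
config_digest <- function(config) {
  js <- jsonlite::toJSON(unclass(config), auto_unbox = TRUE, digits = NA,
                         null = "null")
  tf <- tempfile()
  writeLines(js, tf)
  on.exit(unlink(tf))
  unname(tools::md5sum(tf))
}

#' Write run outputs and a reproducibility manifest
#'
#' Saves phase means/covariances and the final state (RDS), the
#' diagnostics time series (CSV) and a JSON manifest carrying the config
#' digest, seed and schedule summary; re-running with the same manifest
#' settings reproduces the stochastic streams.
#'
#' @param result a [run_da()] result.
#' @param dir output directory (created if needed).
#' @param config optional configuration to digest into the manifest.
#' @return the manifest, invisibly.
#' @export
write_results <- function(result, dir, config = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(dir)) stop("unwritable output directory: ", dir)
  manifest <- result$manifest %||% list()
  if (!is.null(config)) manifest$config_digest <- config_digest(config)
  manifest$format <- "senkflow-results-1"
  if (!is.null(result$moments_analysis))
    saveRDS(result$moments_analysis, file.path(dir, "moments_analysis.rds"))
  if (!is.null(result$moments_forecast))
    saveRDS(result$moments_forecast, file.path(dir, "moments_forecast.rds"))
  if (!is.null(result$state))
    saveRDS(result$state, file.path(dir, "state.rds"))
  if (!is.null(result$diagnostics))
    utils::write.csv(result$diagnostics,
                     file.path(dir, "diagnostics.csv"), row.names = FALSE)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

#' Save / load an observation set
#' @param obs an [observation_set()].
#' @param path file path (`.rds`).
#' @export
save_observations <- function(obs, path) {
  saveRDS(obs, path)
  invisible(path)
}

#' @rdname save_observations
#' @export
load_observations <- function(path) readRDS(path)

#' Export a field snapshot as an ASCII VTK rectilinear grid
#'
#' Cell-centered velocity (interpolated from the faces), pressure and
#' divergence, written as a legacy-format VTK file readable by ParaView.
#'
#' @param field a `velocity_field`.
#' @param grid its [stag_grid()].
#' @param path output file (`.vtk`).
#' @export
write_vtk <- function(field, grid, path) {
  cells <- grid$cells
  Xc <- interpolate_to_centers(field, grid)
  con <- file(path, "w")
  on.exit(close(con))
  wl <- function(...) writeLines(sprintf(...), con)
  wl("# vtk DataFile Version 3.0")
  wl("senkflow snapshot t=%.9g (cell-centered, MAC-interpolated)", field$t)
  wl("ASCII")
  wl("DATASET RECTILINEAR_GRID")
  wl("DIMENSIONS %d %d %d", cells[1], cells[2], cells[3])
  wl("X_COORDINATES %d double", cells[1])
  wl(paste(format(grid$xc, digits = 10), collapse = " "))
  wl("Y_COORDINATES %d double", cells[2])
  wl(paste(format(grid$yc, digits = 10), collapse = " "))
  wl("Z_COORDINATES %d double", cells[3])
  wl(paste(format(grid$zc, digits = 10), collapse = " "))
  wl("POINT_DATA %d", prod(cells))
  wl("VECTORS velocity double")
  writeLines(paste(Xc[, 1], Xc[, 2], Xc[, 3]), con)
  wl("SCALARS pressure double 1")
  wl("LOOKUP_TABLE default")
  writeLines(as.character(as.vector(field$p)), con)
  invisible(path)
}
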