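#' Load a run configuration
#'
#' Reads a YAML configuration with optional top-level blocks `geometry`,
#' `parameters`, `solver` and `scenario`, fills every unspecified value with
#' the package defaults, validates, and rejects unknown keys. An empty file
#' yields the defaults (published parameter tables, default geometry,
#' control scenario).
#'
#' @param path Path to a YAML file.
#' @return A list with elements `parameters` (dimensionless
#'   `parameter_set`), `geometry`, `solver` and `scenario`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg)) cfg <- list()
  known <- c("geometry", "parameters", "solver", "scenario")
  bad <- setdiff(names(cfg), known)
  if (length(bad)) {
    stop("unknown config block(s): ", paste(bad, collapse = ", "),
         "; expected ", paste(known, collapse = ", "), call. = FALSE)
  }
  gcfg <- cfg$geometry %||% list()
  gknown <- c("x_min", "x_max", "x_membrane", "ecm_interval",
              "injection_interval")
  gbad <- setdiff(names(gcfg), gknown)
  if (length(gbad)) {
    stop("unknown geometry key(s): ", paste(gbad, collapse = ", "),
         call. = FALSE)
  }
  geometry <- do.call(transwell_geometry, gcfg)
  parameters <- scenario_overrides(default_dimensionless_parameters(),
                                   cfg$parameters %||% list())
  scfg <- cfg$solver %||% list()
  sknown <- names(formals(solver_config))
  sbad <- setdiff(names(scfg), sknown)
  if (length(sbad)) {
    stop("unknown solver key(s): ", paste(sbad, collapse = ", "), call. = FALSE)
  }
  solver <- do.call(solver_config, scfg)
  sccfg <- cfg$scenario %||% list()
  scknown <- names(formals(make_scenario))
  scbad <- setdiff(names(sccfg), scknown)
  if (length(scbad)) {
    stop("unknown scenario key(s): ", paste(scbad, collapse = ", "),
         call. = FALSE)
  }
  scenario <- do.call(make_scenario, sccfg)
  list(parameters = parameters, geometry = geometry, solver = solver,
       scenario = scenario)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Long-format table of a trajectory
#'
#' One row per (time, cell, variable): columns `t`, `x`, `variable`,
#' `value`.
#'
#' @param trajectory A `transwell_trajectory`.
#' @return A data frame.
#' @export
trajectory_table <- function(trajectory) {
  x <- trajectory$grid$cell_centers
  rows <- lapply(seq_along(trajectory$times), function(i) {
    f <- trajectory$states[[i]]
    data.frame(t = trajectory$times[i],
               x = rep(x, times = ncol(f)),
               variable = rep(colnames(f), each = nrow(f)),
               value = as.vector(f))
  })
  do.call(rbind, rows)
}

#' Run manifest
#'
#' Collects everything needed to reproduce a run bit for bit: scenario,
#' resolved parameters, geometry, solver configuration, package version and
#' solver statistics.
#'
#' @param trajectory A trajectory produced by [run_scenario()].
#' @return A list of class `run_manifest`.
#' @export
run_manifest <- function(trajectory) {
  sc <- attr(trajectory, "scenario")
  p <- attr(trajectory, "parameters")
  if (is.null(sc) || is.null(p)) {
    stop("trajectory lacks scenario/parameter attributes; use run_scenario()",
         call. = FALSE)
  }
  geom <- trajectory$grid$geometry
  structure(list(
    scenario = unclass(sc),
    parameters = stats::setNames(as.numeric(unlist(p)), names(p)),
    geometry = unclass(geom),
    h = trajectory$grid$h,
    package_version = as.character(utils::packageVersion("transwellsim")),
    stats = trajectory$stats
  ), class = "run_manifest")
}

#' Write run outputs
#'
#' Writes the long-format profile table (`profiles.csv`), the observable
#' series (`observables.csv`, one row per output time) and a JSON manifest
#' (`manifest.json`) into a directory.
#'
#' @param trajectory A trajectory from [run_scenario()].
#' @param dir Output directory (created if missing).
#' @return Invisibly, the paths written.
#' @export
write_outputs <- function(trajectory, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(profiles = file.path(dir, "profiles.csv"),
             observables = file.path(dir, "observables.csv"),
             manifest = file.path(dir, "manifest.json"))
  utils::write.csv(trajectory_table(trajectory), paths["profiles"],
                   row.names = FALSE)
  utils::write.csv(observables(trajectory), paths["observables"],
                   row.names = FALSE)
  man <- run_manifest(trajectory)
  jsonlite::write_json(unclass(man), paths["manifest"], auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(paths)
}

#' Re-run a simulation from its manifest
#'
#' Reconstructs scenario, parameters and geometry from a manifest (file or
#' object) and repeats the run; because the model is deterministic the
#' resulting observables are bit-identical to the original run's.
#'
#' @param manifest A `run_manifest` or path to a `manifest.json`.
#' @return A `transwell_trajectory`.
#' @export
rerun_manifest <- function(manifest) {
  if (is.character(manifest)) manifest <- jsonlite::read_json(manifest)
  sc <- manifest$scenario
  scenario <- make_scenario(sc$name,
                            overrides = sc$overrides %||% list(),
                            n0_upper = sc$n0_upper, N1_lower = sc$N1_lower,
                            rho0 = sc$rho0, t_end = sc$t_end,
                            output_times = unlist(sc$output_times))
  pvals <- manifest$parameters
  p <- scenario_overrides(default_dimensionless_parameters(),
                          stats::setNames(as.numeric(unlist(pvals)),
                                          names(pvals)))
  g <- manifest$geometry
  geometry <- transwell_geometry(g$x_min, g$x_max, g$x_membrane,
                                 unlist(g$ecm_interval),
                                 unlist(g$injection_interval))
  run_scenario(scenario, p = p, geometry = geometry, h = manifest$h)
}
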