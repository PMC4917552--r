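#' Read a run configuration file
#'
#' Run configurations are plain-text YAML with up to four sections:
#' `geometry` (fields of [geometry_config()] plus the zone-map settings
#' `cs_start`, `cs_ramp`, `xylem_start`, `xylem_ramp`, `sl_start`),
#' `scenario` (fields of [barrier_scenario()]), `transport` (fields of
#' [transport_defaults()]), and `run` (`P_b_MPa`, `t_max`, `rtol`, `atol`,
#' `steady_tol`, `check_interval`, `initial_condition`, `potential_mode`).
#' Missing fields fall back to the package defaults.
#'
#' @param path path to a YAML file.
#' @return A list with elements `geometry`, `zone_map`, `scenario`, `base`,
#'   `P_b`, `control`, `potential_mode`, ready for [root_model()].
#' @export
read_run_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE)) {
    stop("reading config files requires the 'yaml' package", call. = FALSE)
  }
  cfg <- yaml::read_yaml(path)
  gsec <- cfg$geometry %||% list()
  geo_args <- gsec[intersect(names(gsec), names(formals(geometry_config)))]
  geometry <- build_geometry(do.call(geometry_config, geo_args))
  zm_args <- gsec[intersect(names(gsec),
                            c("cs_start", "cs_ramp", "xylem_start",
                              "xylem_ramp", "sl_start"))]
  zone_map <- do.call(build_zone_map, c(list(geometry), zm_args))
  ssec <- cfg$scenario %||% list()
  scenario <- do.call(barrier_scenario,
                      ssec[intersect(names(ssec), names(formals(barrier_scenario)))])
  tsec <- cfg$transport %||% list()
  base <- do.call(transport_defaults,
                  tsec[intersect(names(tsec), names(formals(transport_defaults)))])
  rsec <- cfg$run %||% list()
  P_b <- (rsec$P_b_MPa %||% -0.5) * 1e6
  ctrl_args <- rsec[intersect(names(rsec), names(formals(simulation_control)))]
  control <- do.call(simulation_control, ctrl_args)
  list(geometry = geometry, zone_map = zone_map, scenario = scenario,
       base = base, P_b = P_b, control = control,
       potential_mode = rsec$potential_mode %||% "electroneutral")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a toy-root configuration file
#'
#' Emits a small, fast configuration (a short root with few cells) useful as
#' a fixture for tests and demonstrations.
#'
#' @param path output YAML path.
#' @param n_axial number of axial cells.
#' @return The path, invisibly.
#' @export
write_toy_config <- function(path, n_axial = 24) {
  if (!requireNamespace("yaml", quietly = TRUE)) {
    stop("writing config files requires the 'yaml' package", call. = FALSE)
  }
  cfg <- list(
    geometry = list(n_axial = as.integer(n_axial), ez_end = 5L,
                    h_min = 20, h_max = 150,
                    cs_start = 6L, xylem_start = 6L, sl_start = 12L),
    scenario = list(scenario_id = "D", seed = 1L),
    run = list(P_b_MPa = -0.5, potential_mode = "electroneutral")
  )
  yaml::write_yaml(cfg, path)
  invisible(path)
}
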