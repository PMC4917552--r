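#' Run one named steady-state scenario
#'
#' Convenience orchestrator: build the geometry, zone map and parameter field
#' for a barrier scenario, assemble the model at the requested transpiration
#' pressure, integrate to steady state and attach the summary statistics.
#'
#' @param scenario_id barrier topology `"A"`, `"B"`, `"C"` or `"D"`.
#' @param P_b xylem-top pressure, Pa (<= 0).
#' @param seed passage-cell seed (scenario D).
#' @param geometry,zone_map optional prebuilt pieces (defaults: the standard
#'   root).
#' @param ions ion roster.
#' @param control [simulation_control()].
#' @param cs_start,xylem_start optional overrides of the development start
#'   cells (offset experiments).
#' @param potential_mode passed to [root_model()].
#' @param base baseline [transport_defaults()].
#' @return The [integrate_to_steady_state()] result with an added
#'   `$summary` tibble ([zone_flux_table()]) and `$efflux`
#'   ([xylem_top_efflux()]).
#' @export
#' @examples
#' \donttest{
#' res <- run_steady_scenario("B", P_b = -0.5e6,
#'   geometry = build_geometry(geometry_config(n_axial = 30)))
#' res$summary
#' }
run_steady_scenario <- function(scenario_id = "D", P_b = -0.5e6, seed = 1L,
                                geometry = build_geometry(),
                                zone_map = NULL, ions = default_ions(),
                                control = simulation_control(),
                                cs_start = 12, xylem_start = 12,
                                potential_mode = "electroneutral",
                                base = transport_defaults()) {
  if (is.null(zone_map)) {
    zone_map <- build_zone_map(geometry, cs_start = cs_start,
                               xylem_start = xylem_start)
  }
  scen <- barrier_scenario(scenario_id, seed = seed)
  pf <- assign_parameters(geometry, zone_map, scen, ions = ions, base = base)
  model <- root_model(geometry, zone_map, pf, P_b = P_b,
                      potential_mode = potential_mode)
  st <- integrate_to_steady_state(model, control)
  st$summary <- zone_flux_table(st)
  st$efflux <- if (geometry$n_axial >= 4L) xylem_top_efflux(st) else NULL
  st
}

#' Xylem-top efflux as a function of transpiration pressure
#'
#' Runs each barrier scenario to steady state over a grid of xylem-top
#' pressures and tabulates the ion and water efflux near the top of the
#' xylem. The default grid spans no transpiration (0 MPa) to strong
#' transpiration (-0.5 MPa) in 0.05 MPa steps.
#'
#' @param scenarios character vector of barrier scenarios.
#' @param P_b_grid pressures, Pa.
#' @param seed passage-cell seed.
#' @param geometry optional geometry.
#' @param control,potential_mode,... passed to [run_steady_scenario()].
#' @return A tibble with one row per (scenario, P_b): columns `scenario`,
#'   `P_b_MPa`, `ion_efflux_mol_s`, `water_flow_m3_s`, `converged`.
#' @export
sweep_pb <- function(scenarios = c("A", "B", "C", "D"),
                     P_b_grid = seq(0, -0.5e6, by = -0.05e6), seed = 1L,
                     geometry = build_geometry(),
                     control = simulation_control(),
                     potential_mode = "electroneutral", ...) {
  grid <- expand.grid(scenario = scenarios, P_b = P_b_grid,
                      stringsAsFactors = FALSE)
  rows <- lapply(seq_len(nrow(grid)), function(r) {
    st <- run_steady_scenario(grid$scenario[r], P_b = grid$P_b[r], seed = seed,
                              geometry = geometry, control = control,
                              potential_mode = potential_mode, ...)
    ef <- st$efflux
    tibble::tibble(scenario = grid$scenario[r], P_b_MPa = grid$P_b[r] / 1e6,
                   ion_efflux_mol_s = ef$ion_flux_mol_s,
                   water_flow_m3_s = ef$water_flow_m3_s,
                   converged = st$converged)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("pb_sweep", class(out))
  out
}

#' Efflux under shifted CS / xylem development starts
#'
#' Explores the effect of moving the first cells of CS and functional-xylem
#' development relative to each other: the coincident default, early or late
#' xylem (unprotected or pre-protected xylem), and early or late CS.
#'
#' @param offsets integer vector of cell offsets applied to each structure in
#'   turn (default +/- 6 cells).
#' @param P_b_grid pressures, Pa.
#' @param scenario_id barrier scenario (default `"B"`, CS only, isolating the
#'   CS/xylem interplay).
#' @param seed,geometry,control,potential_mode,... passed through.
#' @return A tibble with columns `layout`, `cs_start`, `xylem_start`,
#'   `P_b_MPa`, `ion_efflux_mol_s`, `water_flow_m3_s`.
#' @export
run_offset_experiment <- function(offsets = 6L,
                                  P_b_grid = c(-0.1e6, -0.3e6, -0.5e6),
                                  scenario_id = "B", seed = 1L,
                                  geometry = build_geometry(),
                                  control = simulation_control(),
                                  potential_mode = "electroneutral", ...) {
  base_start <- 12L
  layouts <- rbind(
    data.frame(layout = "coincident", cs_start = base_start, xylem_start = base_start),
    data.frame(layout = "xylem_early", cs_start = base_start,
               xylem_start = base_start - offsets),
    data.frame(layout = "cs_late", cs_start = base_start + offsets,
               xylem_start = base_start),
    data.frame(layout = "cs_early", cs_start = base_start - offsets,
               xylem_start = base_start),
    data.frame(layout = "xylem_late", cs_start = base_start,
               xylem_start = base_start + offsets)
  )
  layouts$cs_start <- pmax(layouts$cs_start, 1L)
  layouts$xylem_start <- pmax(layouts$xylem_start, 1L)
  rows <- list()
  for (r in seq_len(nrow(layouts))) {
    for (pb in P_b_grid) {
      st <- run_steady_scenario(scenario_id, P_b = pb, seed = seed,
                                geometry = geometry,
                                cs_start = layouts$cs_start[r],
                                xylem_start = layouts$xylem_start[r],
                                control = control,
                                potential_mode = potential_mode, ...)
      ef <- st$efflux
      rows[[length(rows) + 1L]] <- tibble::tibble(
        layout = layouts$layout[r], cs_start = layouts$cs_start[r],
        xylem_start = layouts$xylem_start[r], P_b_MPa = pb / 1e6,
        ion_efflux_mol_s = ef$ion_flux_mol_s,
        water_flow_m3_s = ef$water_flow_m3_s, converged = st$converged)
    }
  }
  do.call(rbind, rows)
}

#' Run a named experiment scenario
#'
#' Dispatches on the experiment family and (optionally) writes a results
#' directory of plain-text tables: a config echo, the geometry dump, the
#' summary table(s), and per-compartment state snapshots.
#'
#' @param figure one of `"barriers"` (four barrier topologies at one P_b),
#'   `"pb_sweep"`, `"offsets"`, `"transpiration"` (scenario D at 0 and
#'   -0.5 MPa), `"transient"`.
#' @param P_b pressure(s), Pa; a grid for the sweep.
#' @param seed passage-cell seed.
#' @param out_dir optional output directory for text dumps.
#' @param geometry,control,... forwarded to the specific runner.
#' @return A list of results (per scenario / grid point) plus a combined
#'   `summary` tibble.
#' @export
run_scenario <- function(figure = c("barriers", "pb_sweep", "offsets",
                                    "transpiration", "transient"),
                         P_b = -0.5e6, seed = 1L, out_dir = NULL,
                         geometry = build_geometry(),
                         control = simulation_control(), ...) {
  figure <- match.arg(figure)
  res <- switch(figure,
    barriers = {
      runs <- lapply(c("A", "B", "C", "D"), function(sid) {
        run_steady_scenario(sid, P_b = P_b, seed = seed, geometry = geometry,
                            control = control, ...)
      })
      names(runs) <- c("A", "B", "C", "D")
      summ <- do.call(rbind, lapply(names(runs), function(sid) {
        tab <- runs[[sid]]$summary
        tab$scenario <- sid
        tab
      }))
      list(runs = runs, summary = summ)
    },
    pb_sweep = {
      tab <- sweep_pb(P_b_grid = if (length(P_b) > 1) P_b else
                        seq(0, -0.5e6, by = -0.05e6),
                      seed = seed, geometry = geometry, control = control, ...)
      list(summary = tab)
    },
    offsets = {
      tab <- run_offset_experiment(P_b_grid = P_b, seed = seed,
                                   geometry = geometry, control = control, ...)
      list(summary = tab)
    },
    transpiration = {
      runs <- lapply(c(0, -0.5e6), function(pb) {
        run_steady_scenario("D", P_b = pb, seed = seed, geometry = geometry,
                            control = control, ...)
      })
      names(runs) <- c("Pb=0", "Pb=-0.5MPa")
      summ <- do.call(rbind, lapply(names(runs), function(nm) {
        tab <- runs[[nm]]$summary; tab$condition <- nm; tab
      }))
      list(runs = runs, summary = summ)
    },
    transient = {
      tr <- run_transient_addition(geometry, scenario = barrier_scenario("D", seed = seed),
                                   P_b = P_b[1], ...)
      list(transient = tr,
           summary = tibble::tibble(t_steady_added_days = tr$t_steady_added / 86400,
                                    converged = tr$converged))
    })
  if (!is.null(out_dir)) write_scenario_results(res, figure, out_dir, geometry)
  invisible(res)
}

write_scenario_results <- function(res, figure, out_dir, geometry) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(geometry_table(geometry),
                   file.path(out_dir, "geometry.csv"), row.names = FALSE)
  if (!is.null(res$summary)) {
    utils::write.csv(res$summary, file.path(out_dir, paste0(figure, "_summary.csv")),
                     row.names = FALSE)
  }
  if (!is.null(res$runs)) {
    for (nm in names(res$runs)) {
      st <- res$runs[[nm]]
      utils::write.csv(state_table(st),
                       file.path(out_dir, paste0("state_", gsub("[^A-Za-z0-9]", "_", nm), ".csv")),
                       row.names = FALSE)
    }
  }
  invisible(out_dir)
}

#' Tabulate a state snapshot
#'
#' One row per compartment with concentrations, pressure and potential.
#'
#' @param steady a steady-state result.
#' @return A tibble.
#' @export
state_table <- function(steady) {
  model <- steady$model
  n <- model$n_axial
  tab <- tibble::tibble(
    layer = rep(.layer_names, times = n),
    j = rep(seq_len(n), each = 5L),
    P_Pa = steady$pressure,
    psi_V = steady$potential
  )
  conc <- as.data.frame(steady$state)
  names(conc) <- paste0("c_", model$ions$name)
  cbind(tab, conc)
}
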