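#' Control settings for time integration
#'
#' The stiff ODE system is integrated with an implicit sparse BDF method
#' (`deSolve::lsodes`) using the compartment-connectivity Jacobian sparsity.
#' Steady state is declared when the relative derivative norm — the largest
#' net mole rate of any compartment relative to its own membrane-exchange
#' capacity (see the methods vignette) — stays at or below `steady_tol` at
#' two consecutive checks.
#'
#' @param t_max hard cap on model time, s (default 10 days).
#' @param rtol,atol integrator tolerances.
#' @param steady_tol relative derivative-norm threshold.
#' @param check_interval spacing of steady-state checks, s.
#' @param initial_condition `"empty_root"` (no ions in the root),
#'   `"soil_equilibrium"` (every compartment at the soil concentrations) or
#'   `"from_state"` (supply `state0`).
#' @param state0 concentration matrix (compartment x species) when
#'   `initial_condition = "from_state"`.
#' @param method `"lsodes"` (sparse stiff BDF with grouped finite-difference
#'   Jacobian on the compartment-connectivity pattern; default),
#'   `"lsodes_analytic"` (same pattern, analytic on-pattern Jacobian with
#'   exact elliptic feedback — slower but a useful cross-check), or any
#'   other `deSolve::ode` method name for small systems.
#' @param hmax maximum internal step size, s.
#' @return A list of validated control settings.
#' @export
simulation_control <- function(t_max = 10 * 86400, rtol = 1e-6, atol = 1e-6,
                               steady_tol = 1e-3, check_interval = 21600,
                               initial_condition = c("empty_root",
                                                     "soil_equilibrium",
                                                     "from_state"),
                               state0 = NULL, method = "lsodes",
                               hmax = 10800) {
  initial_condition <- match.arg(initial_condition)
  if (t_max <= 0) stop("t_max must be positive", call. = FALSE)
  if (rtol <= 0 || atol <= 0 || steady_tol <= 0) {
    stop("tolerances must be positive", call. = FALSE)
  }
  if (check_interval <= 0 || check_interval > t_max) {
    stop("check_interval must lie in (0, t_max]", call. = FALSE)
  }
  if (initial_condition == "from_state" && is.null(state0)) {
    stop("initial_condition 'from_state' needs state0", call. = FALSE)
  }
  if (hmax <= 0) stop("hmax must be positive", call. = FALSE)
  list(t_max = t_max, rtol = rtol, atol = atol, steady_tol = steady_tol,
       check_interval = check_interval, initial_condition = initial_condition,
       state0 = state0, method = method, hmax = hmax)
}

initial_state <- function(net, control) {
  switch(control$initial_condition,
         empty_root = matrix(0, net$ncomp, net$ns),
         soil_equilibrium = matrix(net$ions$soil_concentration,
                                   net$ncomp, net$ns, byrow = TRUE),
         from_state = {
           s <- control$state0
           stopifnot(is.matrix(s), nrow(s) == net$ncomp, ncol(s) == net$ns)
           s
         })
}

# one deSolve integration over the given output times; returns the deSolve
# matrix (rows = times)
integrate_network <- function(net, y0, times, control) {
  func <- function(t, y, p) {
    list(as.vector(network_rhs(net, matrix(y, net$ncomp, net$ns))$dC))
  }
  neq <- net$ncomp * net$ns
  if (control$method %in% c("lsodes", "lsodes_analytic")) {
    inz <- jacobian_sparsity(net)
    nnz <- nrow(inz)
    lrw <- as.integer(min(2^31 - 1, 30 * neq + 30 * nnz + 10000))
    liw <- as.integer(min(2^31 - 1, 35 + neq + 2 * nnz + 1000))
    jacvec <- NULL
    if (identical(control$method, "lsodes_analytic")) {
      # analytic on-pattern Jacobian, cached per (t, y), served column-wise
      cache <- new.env(parent = emptyenv())
      cache$t <- NA_real_; cache$J <- NULL; cache$y <- NULL
      jacvec <- function(t, y, j, p) {
        if (!identical(t, cache$t) || !identical(y, cache$y)) {
          cache$J <- local_jacobian(net, matrix(y, net$ncomp, net$ns))
          cache$t <- t; cache$y <- y
        }
        Jm <- cache$J
        col <- numeric(neq)
        p1 <- Jm@p[j] + 1L; p2 <- Jm@p[j + 1L]
        if (p2 >= p1) {
          idx <- p1:p2
          col[Jm@i[idx] + 1L] <- Jm@x[idx]
        }
        col
      }
    }
    deSolve::ode(y = as.vector(y0), times = times, func = func, parms = NULL,
                 method = "lsodes", sparsetype = "sparseusr", inz = inz,
                 jacvec = jacvec, maxsteps = 20000, hmax = control$hmax,
                 lrw = lrw, liw = liw, rtol = control$rtol, atol = control$atol)
  } else {
    deSolve::ode(y = as.vector(y0), times = times, func = func, parms = NULL,
                 method = control$method, rtol = control$rtol,
                 atol = control$atol)
  }
}

#' Integrate the model to steady state
#'
#' Integrates the stiff concentration ODE from the configured initial
#' condition up to `t_max`, evaluating the relative derivative norm at each
#' check time. Steady state is declared at the first check where the norm has
#' been at or below `steady_tol` for two consecutive checks; the returned
#' fields are taken from the final integrated state (the most relaxed one).
#' If the norm never satisfies the criterion a warning is raised and
#' `converged` is `FALSE`.
#'
#' @param model a [root_model()] or [transport_network()].
#' @param control a [simulation_control()].
#' @return An object of class `root_steady_state`: list with `state`
#'   (compartment x species concentrations, mol m^-3), `pressure` (Pa),
#'   `potential` (V), `fluxes` (interface flux snapshot with components
#'   `Jv`, `J_diff`, `J_elec`, `J_conv`, `J_total`), `t_reached` (s),
#'   `converged`, `norm` (norm at exit), `norms` (per-check trajectory),
#'   and the `model`.
#' @export
integrate_to_steady_state <- function(model, control = simulation_control()) {
  net <- as_network(model)
  y0 <- initial_state(net, control)
  times <- unique(c(seq(0, control$t_max, by = control$check_interval),
                    control$t_max))
  out <- integrate_network(net, y0, times, control)
  nt <- nrow(out)
  norms <- numeric(nt)
  for (r in seq_len(nt)) {
    cmat <- matrix(out[r, -1], net$ncomp, net$ns)
    norms[r] <- steady_norm(net, network_rhs(net, cmat)$dC)
  }
  below <- norms <= control$steady_tol
  hit <- which(below & c(FALSE, below[-nt]))
  converged <- length(hit) > 0
  t_reached <- if (converged) out[hit[1], 1] else out[nt, 1]
  if (!converged) {
    warning(sprintf("steady state not reached by t_max = %.3g s (norm %.3g > %.3g)",
                    control$t_max, norms[nt], control$steady_tol),
            call. = FALSE)
  }
  final <- matrix(out[nt, -1], net$ncomp, net$ns)
  fl <- network_rhs(net, final, want_fields = TRUE)$fields
  structure(list(state = final, pressure = fl$P, potential = fl$psi,
                 fluxes = fl[c("Jv", "J_diff", "J_elec", "J_conv", "J_total")],
                 t_reached = t_reached, converged = converged,
                 norm = norms[nt], norms = norms, check_times = out[, 1],
                 model = model, control = control),
            class = "root_steady_state")
}

#' @export
print.root_steady_state <- function(x, ...) {
  cat(sprintf("Steady-state result: %s at t = %.3g h (norm %.2e)\n",
              if (x$converged) "converged" else "NOT converged",
              x$t_reached / 3600, x$norm))
  invisible(x)
}

#' Two-stage transient: adding a new salt pair to an equilibrated root
#'
#' Stage 1 brings the root to steady state with the resident ion pair alone.
#' Stage 2 then adds a second pair at the soil concentration with zero
#' initial concentration inside the root and follows the added species over
#' time, recording snapshots and the model time at which the added species'
#' relative derivative norm first satisfies the steady-state criterion at two
#' consecutive checks.
#'
#' @param geometry,zone_map,scenario as for [root_model()];
#'   `scenario` is a [barrier_scenario()].
#' @param P_b xylem-top pressure, Pa.
#' @param resident_ions roster for stage 1 (default one 100 mM pair).
#' @param added_ions roster for the added pair.
#' @param snapshot_times times after addition at which states are recorded, s
#'   (defaults: 15 min, 2 h, 4 h).
#' @param control_stage1,control_stage2 [simulation_control()] settings;
#'   stage 2 defaults to half-hourly steady checks for good time resolution.
#' @param constants,potential_mode passed to [root_model()].
#' @param base baseline [transport_defaults()].
#' @return An object of class `root_transient`: list with `t_steady_added`
#'   (s), `converged`, `snapshots` (list of concentration matrices for the
#'   full 4-species roster at `snapshot_times` and at the final time),
#'   `snapshot_times`, `added_species` (column indices), the stage-1 result
#'   and the stage-2 model.
#' @export
run_transient_addition <- function(geometry, zone_map = build_zone_map(geometry),
                                   scenario = barrier_scenario("D"),
                                   P_b = -0.5e6,
                                   resident_ions = default_ions(n_pairs = 1),
                                   added_ions = {
                                     a <- default_ions(n_pairs = 1)
                                     a$name <- paste0(a$name, "_added"); a
                                   },
                                   snapshot_times = c(900, 7200, 14400),
                                   control_stage1 = simulation_control(),
                                   control_stage2 = simulation_control(
                                     check_interval = 1800),
                                   constants = physical_constants(),
                                   potential_mode = "electroneutral",
                                   base = transport_defaults()) {
  # the passage-cell layout must be identical in both stages
  mask <- if (scenario$scenario_id == "D") {
    sample_passage_cells(zone_map, scenario$seed, scenario$passage_decay)
  }
  pf1 <- assign_parameters(geometry, zone_map, scenario, ions = resident_ions,
                           base = base, mask = mask)
  m1 <- root_model(geometry, zone_map, pf1, P_b = P_b, constants = constants,
                   potential_mode = potential_mode)
  st1 <- integrate_to_steady_state(m1, control_stage1)
  if (!st1$converged) {
    stop("stage 1 (resident pair) did not reach steady state; aborting stage 2",
         call. = FALSE)
  }

  full_ions <- rbind(resident_ions, added_ions)
  pf2 <- assign_parameters(geometry, zone_map, scenario, ions = full_ions,
                           base = base, mask = mask)
  m2 <- root_model(geometry, zone_map, pf2, P_b = P_b, constants = constants,
                   potential_mode = potential_mode)
  net2 <- m2$network
  ns1 <- nrow(resident_ions)
  added_cols <- ns1 + seq_len(nrow(added_ions))
  y0 <- matrix(0, net2$ncomp, net2$ns)
  y0[, seq_len(ns1)] <- st1$state

  ctrl <- control_stage2
  ctrl$initial_condition <- "from_state"
  ctrl$state0 <- y0
  times <- sort(unique(c(seq(0, ctrl$t_max, by = ctrl$check_interval),
                         snapshot_times[snapshot_times <= ctrl$t_max],
                         ctrl$t_max)))
  out <- integrate_network(net2, y0, times, ctrl)
  nt <- nrow(out)
  norms <- numeric(nt)
  for (r in seq_len(nt)) {
    cmat <- matrix(out[r, -1], net2$ncomp, net2$ns)
    norms[r] <- steady_norm(net2, network_rhs(net2, cmat)$dC,
                            species = added_cols)
  }
  below <- norms <= ctrl$steady_tol
  # ignore t = 0 (the added species start identically at zero everywhere)
  below[1] <- FALSE
  hit <- which(below & c(FALSE, below[-nt]))
  converged <- length(hit) > 0
  t_steady <- if (converged) out[hit[1], 1] else out[nt, 1]
  if (!converged) {
    warning("added species did not reach steady state within t_max", call. = FALSE)
  }
  snap_idx <- vapply(snapshot_times, function(ts) which.min(abs(out[, 1] - ts)),
                     integer(1))
  snapshots <- lapply(c(snap_idx, nt), function(r) {
    matrix(out[r, -1], net2$ncomp, net2$ns,
           dimnames = list(NULL, full_ions$name))
  })
  names(snapshots) <- c(sprintf("t=%gs", out[snap_idx, 1]), "final")
  structure(list(t_steady_added = t_steady, converged = converged,
                 snapshots = snapshots,
                 snapshot_times = c(out[snap_idx, 1], out[nt, 1]),
                 norms = norms, check_times = out[, 1],
                 added_species = added_cols, stage1 = st1, model = m2),
            class = "root_transient")
}

#' @export
print.root_transient <- function(x, ...) {
  cat(sprintf("Transient ion addition: added pair %s steady at t = %.2f days\n",
              if (x$converged) "reached" else "did NOT reach",
              x$t_steady_added / 86400))
  invisible(x)
}
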