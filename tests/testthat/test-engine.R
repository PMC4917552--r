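test_that("closed two-box system equilibrates to the analytic mean", {
  net <- closed_two_box() # equal volumes
  c0 <- 100
  y0 <- matrix(c(0, 2 * c0, 0, 2 * c0), 2, 2)
  ctrl <- simulation_control(t_max = 3e6, check_interval = 5e4,
                             initial_condition = "from_state", state0 = y0,
                             method = "lsoda")
  res <- integrate_to_steady_state(net, ctrl)
  expect_true(res$converged)
  expect_equal(as.vector(res$state), rep(c0, 4), tolerance = 1e-5)
  # total moles conserved along the way
  total0 <- sum(y0 * net$volumes)
  expect_equal(sum(res$state * net$volumes), total0, tolerance = 1e-6)
})

test_that("steady state is re-confirmed by an independent rhs evaluation", {
  model <- toy_root_model("B", P_b = -0.3e6)
  res <- integrate_to_steady_state(model, simulation_control())
  expect_true(res$converged)
  dC <- root_rhs(model, res$state)
  norm <- rhizoflux:::steady_norm(model$network, dC)
  expect_lte(norm, res$control$steady_tol)
})

test_that("steady state is independent of the initial condition", {
  model <- toy_root_model("D", P_b = -0.5e6)
  s_empty <- integrate_to_steady_state(model, simulation_control())
  s_soil <- integrate_to_steady_state(
    model, simulation_control(initial_condition = "soil_equilibrium"))
  rel <- abs(s_empty$state - s_soil$state) /
    max(model$ions$soil_concentration)
  expect_lt(max(rel), 0.001) # within 0.1 % per compartment
})

test_that("identical configurations reproduce bit-comparable results", {
  m1 <- toy_root_model("D", seed = 11)
  m2 <- toy_root_model("D", seed = 11)
  r1 <- integrate_to_steady_state(m1, simulation_control())
  r2 <- integrate_to_steady_state(m2, simulation_control())
  expect_lt(max(abs(r1$state - r2$state)) / 100, 1e-12)
  expect_identical(m1$params$mask$passage, m2$params$mask$passage)
})

test_that("charge symmetry is preserved over time", {
  model <- toy_root_model("D")
  res <- integrate_to_steady_state(model, simulation_control())
  ns <- model$ns
  cation_cols <- which(model$ions$valence > 0)
  anion_cols <- which(model$ions$valence < 0)
  # pairs stay equal to within the integrator's own error control
  expect_lt(max(abs(res$state[, cation_cols[1]] - res$state[, anion_cols[1]])) /
              100, 1e-6)
  expect_lt(max(abs(res$potential)), 1e-6)
})

test_that("both potential modes agree at a charge-symmetric steady state", {
  model_e <- toy_root_model("B", potential_mode = "electroneutral")
  res <- integrate_to_steady_state(model_e, simulation_control())
  # enforce exact pairing (the integrator leaves ~1e-7 roundoff asymmetry,
  # which the Poisson gain F/(eps0*eps_r) would amplify enormously — the
  # Poisson mode is only meaningful for exactly neutral fields)
  sym <- res$state
  cations <- which(model_e$ions$valence > 0)
  anions <- which(model_e$ions$valence < 0)
  sym[, anions] <- sym[, cations]
  psi_p <- solve_potential(model_e, sym, mode = "poisson")
  psi_e <- solve_potential(model_e, sym, mode = "electroneutral")
  expect_lt(max(abs(psi_p)), 1e-9)
  expect_lt(max(abs(psi_e)), 1e-9)
  # the steady state satisfies the Poisson-mode rhs as well
  model_p <- toy_root_model("B", potential_mode = "poisson")
  dC <- root_rhs(model_p, sym)
  expect_lte(rhizoflux:::steady_norm(model_p$network, dC), 1e-3)
})

test_that("solute content changes match the boundary-flux integral", {
  model <- toy_root_model("C", P_b = -0.3e6)
  net <- model$network
  y0 <- rhizoflux:::initial_state(net, simulation_control())
  times <- seq(0, 7200, by = 90)
  out <- rhizoflux:::integrate_network(net, y0, times,
                                       simulation_control(rtol = 1e-8,
                                                          atol = 1e-8))
  bnd <- which(net$btype != "none")
  sgn <- ifelse(net$to[bnd] > 0, 1, -1) # inflow positive into the root
  rate <- numeric(length(times))
  total <- numeric(length(times))
  for (r in seq_along(times)) {
    cmat <- matrix(out[r, -1], net$ncomp, net$ns)
    fl <- rhizoflux:::network_fluxes(net, cmat)
    rate[r] <- sum(sgn * net$area[bnd] * rowSums(fl$J_total[bnd, , drop = FALSE]))
    total[r] <- sum(cmat * net$volumes)
  }
  integral <- sum(diff(times) * (rate[-1] + rate[-length(rate)]) / 2)
  gained <- total[length(total)] - total[1]
  expect_equal(gained, integral, tolerance = 1e-3)
})

test_that("unconverged integration warns and flags the result", {
  model <- toy_root_model("D")
  expect_warning(
    res <- integrate_to_steady_state(
      model, simulation_control(t_max = 600, check_interval = 300)),
    "not reached")
  expect_false(res$converged)
})

test_that("transient addition starts clean and matches stage 1 at t = 0", {
  geom <- toy_geometry()
  zm <- toy_zone_map(geom)
  tr <- run_transient_addition(
    geom, zm, barrier_scenario("D", seed = 3), P_b = -0.5e6,
    snapshot_times = c(900, 3600),
    control_stage2 = simulation_control(t_max = 4 * 86400,
                                        check_interval = 1800))
  expect_true(tr$converged)
  expect_gt(tr$t_steady_added, 0)
  # resident columns at addition equal the stage-1 steady state by construction
  expect_equal(dim(tr$snapshots[[1]]), c(geom$n_axial * 5L, 4L))
  # added species grow from zero and stay below the resident pair early on
  s15 <- tr$snapshots[[1]]
  expect_true(all(s15[, tr$added_species] >= -1e-6))
  expect_lt(max(s15[, tr$added_species]), max(s15[, 1:2]))
  # at the final time both pairs approach the same field (identical physics)
  fin <- tr$snapshots[["final"]]
  expect_equal(fin[, 1], fin[, 3], tolerance = 0.02)
})

test_that("splitting the mature-DZ cells changes the xylem efflux only modestly", {
  geom1 <- toy_geometry(n_axial = 24) # ramps complete by cell 10
  st1 <- run_steady_scenario("B", P_b = -0.3e6, geometry = geom1,
                             zone_map = toy_zone_map(geom1))
  h1 <- geom1$cell_heights
  h2 <- c(h1[1:10], rep(h1[11:24] / 2, each = 2)) # halve cells 11..24
  geom2 <- build_geometry(geometry_config(n_axial = 38, ez_end = 5,
                                          cell_heights = h2))
  zm2 <- build_zone_map(geom2, cs_start = 6, cs_ramp = 4,
                        xylem_start = 6, xylem_ramp = 4, sl_start = 13)
  pf2 <- assign_parameters(geom2, zm2, barrier_scenario("B"))
  m2 <- root_model(geom2, zm2, pf2, P_b = -0.3e6,
                   potential_mode = "electroneutral")
  st2 <- integrate_to_steady_state(m2, simulation_control())
  e1 <- xylem_top_efflux(st1)$ion_flux_mol_s        # between cells 21 | 22
  e2 <- xylem_top_efflux(st2, cells_below = 6L)$ion_flux_mol_s # same position
  expect_lt(abs(e2 - e1) / abs(e1), 0.05)
})
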