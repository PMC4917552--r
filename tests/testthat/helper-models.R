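# Shared fixture builders. Everything is generated in code; no stored data.

# small root: short EZ, early barriers, SL region present
toy_geometry <- function(n_axial = 24, ez_end = 5) {
  build_geometry(geometry_config(n_axial = n_axial, ez_end = ez_end))
}

toy_zone_map <- function(geometry, cs_start = 6, xylem_start = 6, sl_start = 12) {
  build_zone_map(geometry, cs_start = cs_start, cs_ramp = 4,
                 xylem_start = xylem_start, xylem_ramp = 4, sl_start = sl_start)
}

toy_root_model <- function(scenario_id = "D", P_b = -0.5e6, seed = 1,
                           n_axial = 24, potential_mode = "electroneutral",
                           ions = default_ions(), ...) {
  geom <- toy_geometry(n_axial = n_axial)
  zm <- toy_zone_map(geom, ...)
  pf <- assign_parameters(geom, zm, barrier_scenario(scenario_id, seed = seed),
                          ions = ions)
  root_model(geom, zm, pf, ions = ions, P_b = P_b,
             potential_mode = potential_mode)
}

# closed two-compartment box joined by a single membrane; no boundaries
closed_two_box <- function(V = c(1e-12, 1e-12), area = 1e-9, Gw = 5.5e-14,
                           k = 3e-9, sigma = 0.5,
                           ions = default_ions(n_pairs = 1)) {
  ns <- nrow(ions)
  interfaces <- data.frame(from = 1L, to = 2L, area = area, Gw = Gw, dz = 0,
                           btype = "none", bP = NA_real_,
                           poisson_d = NA_real_)
  transport_network(V, interfaces,
                    k = matrix(k, 1, ns), sigma = matrix(sigma, 1, ns),
                    ions = ions, potential_mode = "electroneutral")
}

# single compartment between two fixed-pressure reservoirs
one_box_two_reservoirs <- function(P1, P2, W1 = 1e-20, W2 = W1,
                                   ions = default_ions(n_pairs = 1,
                                                       soil_concentration = 0)) {
  ns <- nrow(ions)
  interfaces <- data.frame(from = c(0L, 1L), to = c(1L, 0L),
                           area = 1e-9, Gw = c(W1, W2) / 1e-9, dz = 0,
                           btype = "soil", bP = c(P1, P2),
                           poisson_d = NA_real_)
  transport_network(1e-12, interfaces,
                    k = matrix(0, 2, ns), sigma = matrix(0.5, 2, ns),
                    ions = ions, potential_mode = "electroneutral")
}

# n x n grid of unit boxes for the Poisson oracle; the left column is
# grounded through Dirichlet faces
poisson_grid <- function(n = 3, spacing = 1e-5, area = 1e-10,
                         ions = default_ions(n_pairs = 1)) {
  idx <- function(i, j) (j - 1L) * n + i
  from <- integer(0); to <- integer(0); btype <- character(0)
  for (j in seq_len(n)) {
    for (i in seq_len(n)) {
      if (i < n) { from <- c(from, idx(i, j)); to <- c(to, idx(i + 1L, j)); btype <- c(btype, "none") }
      if (j < n) { from <- c(from, idx(i, j)); to <- c(to, idx(i, j + 1L)); btype <- c(btype, "none") }
    }
  }
  # grounded faces on the left column
  for (j in seq_len(n)) { from <- c(from, 0L); to <- c(to, idx(1L, j)); btype <- c(btype, "soil") }
  ni <- length(from)
  interfaces <- data.frame(from = from, to = to, area = area, Gw = 1e-14,
                           dz = 0, btype = btype,
                           bP = ifelse(btype == "soil", 0, NA_real_),
                           poisson_d = spacing)
  ns <- nrow(ions)
  transport_network(rep(spacing^3, n * n), interfaces,
                    k = matrix(3e-9, ni, ns), sigma = matrix(0.5, ni, ns),
                    ions = ions, potential_mode = "poisson")
}

expect_rel_equal <- function(actual, expected, tol = 1e-8) {
  expect_lt(abs(actual - expected) / max(abs(expected), .Machine$double.eps),
            tol)
}
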