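#' Van't Hoff osmotic pressure
#'
#' For dilute solutions the osmotic pressure is `pi = R * T * sum(c)` over
#' all dissolved species.
#'
#' @param c concentrations of the species in one compartment, mol m^-3.
#' @param constants [physical_constants()].
#' @return Osmotic pressure, Pa.
#' @export
#' @examples
#' osmotic_pressure(rep(100, 4)) # four species at 100 mM, ~9.9e5 Pa
osmotic_pressure <- function(c, constants = physical_constants()) {
  stopifnot(all(is.finite(c)))
  constants$R * constants$T * sum(c)
}

#' Water volume flux across one interface
#'
#' Membrane interfaces follow the Kedem-Katchalsky law
#' `Jv = Lp * ((P_a - P_b - rho*g*dz) - R*T*sum(sigma_i * (c_a,i - c_b,i)))`;
#' open channels (mature xylem lumen) follow Darcy's law
#' `Jv = (k_channel / mu) * ((P_a - P_b) / dz - rho*g)`, with `a` the lower
#' compartment. Positive flux runs from side `a` to side `b`; `dz` is the
#' elevation gain from `a` to `b` (0 for radial interfaces).
#'
#' @param Lp membrane water permeability, m s^-1 Pa^-1 (SI; see
#'   [transport_defaults()] for the MPa conversion).
#' @param sigma per-species reflection coefficients.
#' @param P_a,P_b hydraulic pressures on the two sides, Pa.
#' @param c_a,c_b per-species concentrations on the two sides, mol m^-3.
#' @param dz elevation gain from a to b, m.
#' @param constants [physical_constants()].
#' @param open_channel if `TRUE`, use Darcy flow.
#' @param channel_permeability Darcy permeability, m^2 (open channel only).
#' @return Volume flux density Jv, m s^-1.
#' @export
#' @examples
#' water_flux(5.5e-14, 0.5, P_a = 1e5, P_b = 0, c_a = 0, c_b = 0) # 5.5e-9 m/s
water_flux <- function(Lp, sigma, P_a, P_b, c_a = 0, c_b = 0, dz = 0,
                       constants = physical_constants(),
                       open_channel = FALSE, channel_permeability = NULL) {
  if (open_channel) {
    if (dz <= 0) stop("open-channel (axial) interfaces need dz > 0", call. = FALSE)
    if (is.null(channel_permeability) || channel_permeability <= 0) {
      stop("open_channel requires a positive channel_permeability", call. = FALSE)
    }
    return((channel_permeability / constants$mu) *
             ((P_a - P_b) / dz - constants$rho * constants$g))
  }
  if (length(c_a) != length(c_b) ||
      (length(sigma) != 1L && length(sigma) != length(c_a))) {
    stop("sigma, c_a and c_b must be conformable", call. = FALSE)
  }
  Lp * ((P_a - P_b - constants$rho * constants$g * dz) -
          constants$R * constants$T * sum(sigma * (c_a - c_b)))
}

#' Extended Nernst-Planck ion flux across one interface
#'
#' The per-species flux combines diffusion, electromigration and convection,
#' evaluated with the arithmetic-mean interface concentration
#' `cbar = (c_a + c_b) / 2`:
#' `J_diff = k * (c_a - c_b)`,
#' `J_elec = k * z * (F / (R*T)) * cbar * (psi_a - psi_b)`,
#' `J_conv = (1 - sigma) * cbar * Jv`.
#' The decomposition is exact: `J_total = J_diff + J_elec + J_conv`.
#'
#' @param k solute diffusive permeability, m s^-1.
#' @param sigma reflection coefficient.
#' @param z signed valence.
#' @param c_a,c_b concentrations on the two sides, mol m^-3.
#' @param psi_a,psi_b electric potentials on the two sides, V.
#' @param Jv water volume flux from a to b, m s^-1.
#' @param constants [physical_constants()].
#' @return A list with components `diffusive`, `electric`, `convective`,
#'   `total`, each mol m^-2 s^-1 (vectorised over species).
#' @export
#' @examples
#' ion_flux(3e-9, 0.5, +1, c_a = 150, c_b = 100, psi_a = 0, psi_b = 0, Jv = 0)
ion_flux <- function(k, sigma, z, c_a, c_b, psi_a = 0, psi_b = 0, Jv = 0,
                     constants = physical_constants()) {
  cbar <- (c_a + c_b) / 2
  J_diff <- k * (c_a - c_b)
  J_elec <- k * z * (constants$F / (constants$R * constants$T)) * cbar *
    (psi_a - psi_b)
  J_conv <- (1 - sigma) * cbar * Jv
  list(diffusive = J_diff, electric = J_elec, convective = J_conv,
       total = J_diff + J_elec + J_conv)
}

#' Quasi-static pressure field of a model
#'
#' Solves the linear volume-conservation system: for every rigid,
#' water-filled compartment the areas-weighted sum of interface water fluxes
#' vanishes. Boundary terms use the hydrostatic soil profile and the fixed
#' xylem-top pressure. The returned object carries the incompressibility
#' residual (largest net volume inflow relative to the largest interface
#' volume flow).
#'
#' @param model a [root_model()] or [transport_network()].
#' @param state concentration state: matrix (compartment x species),
#'   mol m^-3.
#' @return An object of class `pressure_field`: list with `P` (Pa, per
#'   compartment), `Jv` (m s^-1, per interface) and `residual`.
#' @export
solve_pressure <- function(model, state) {
  net <- as_network(model)
  cmat <- as_state_matrix(net, state)
  cc <- interface_concentrations(net, cmat)
  q <- interface_q(net, cc$ca, cc$cb)
  P <- solve_pressure_core(net, q)
  pp <- interface_pressures(net, P)
  Jv <- net$Gw * (pp$Pa - pp$Pb - q)
  structure(list(P = P, Jv = Jv, residual = pressure_residual(net, Jv)),
            class = "pressure_field")
}

#' Quasi-static electric potential of a model
#'
#' `mode = "poisson"` solves the finite-volume discretisation of Poisson's
#' equation on the compartment centres, with the potential grounded (0 V) at
#' the outer soil boundary and zero normal derivative at the axis, top and
#' bottom. `mode = "electroneutral"` instead chooses the potential so that
#' the net charge flux into every compartment vanishes (zero-current
#' approximation for stiff cases). Both return identical (zero) fields for
#' charge-symmetric states.
#'
#' @param model a [root_model()] or [transport_network()].
#' @param state concentration state matrix (compartment x species).
#' @param mode `"poisson"` or `"electroneutral"`; defaults to the model's
#'   configured mode.
#' @return Numeric vector of potentials, V, per compartment.
#' @export
solve_potential <- function(model, state, mode = NULL) {
  net <- as_network(model)
  if (!is.null(mode)) net$potential_mode <- match.arg(mode, c("poisson", "electroneutral"))
  cmat <- as_state_matrix(net, state)
  cc <- interface_concentrations(net, cmat)
  Jv <- NULL
  if (net$potential_mode == "electroneutral") {
    q <- interface_q(net, cc$ca, cc$cb)
    P <- solve_pressure_core(net, q)
    pp <- interface_pressures(net, P)
    Jv <- net$Gw * (pp$Pa - pp$Pb - q)
  }
  solve_potential_core(net, cmat, cc$ca, cc$cb, Jv = Jv)
}

#' Time derivative of the concentration state
#'
#' One full right-hand-side evaluation of the transport model: solve the
#' quasi-static potential and pressure fields, evaluate every interface flux,
#' and return the per-compartment concentration rates
#' `dc/dt = (1/V) * sum(area * J_total)` with inward-positive signs.
#'
#' @param model a [root_model()] or [transport_network()].
#' @param state concentration state matrix (compartment x species).
#' @param fields if `TRUE`, also return the flux/pressure/potential snapshot.
#' @return A matrix (compartment x species) of rates, mol m^-3 s^-1; with
#'   `fields = TRUE` a list with elements `dC` and `fields`.
#' @export
root_rhs <- function(model, state, fields = FALSE) {
  net <- as_network(model)
  cmat <- as_state_matrix(net, state)
  out <- network_rhs(net, cmat, want_fields = fields)
  if (fields) out else out$dC
}

as_network <- function(model) {
  if (inherits(model, "root_model")) model$network
  else if (inherits(model, "transport_network")) model
  else stop("expected a root_model or transport_network", call. = FALSE)
}

as_state_matrix <- function(net, state) {
  if (is.matrix(state)) {
    stopifnot(nrow(state) == net$ncomp, ncol(state) == net$ns)
    state
  } else {
    matrix(as.numeric(state), net$ncomp, net$ns)
  }
}
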