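#' Low-level compartment transport network
#'
#' A transport network is a set of well-mixed, rigid, water-filled
#' compartments joined by interfaces. Every interface is either a membrane
#' (Kedem-Katchalsky water flux, extended Nernst-Planck ion flux) or an open
#' channel (Darcy water flow, free diffusion, zero reflection). Boundary
#' interfaces connect a compartment to an external reservoir with a fixed
#' pressure and either fixed concentrations (`"soil"`) or a no-gradient
#' outflow condition (`"open_top"`, purely convective solute flux at the
#' compartment's own concentration).
#'
#' [root_model()] builds the root-specific network; this constructor is
#' exposed so that small bespoke networks (toy fixtures, closed boxes) can be
#' built directly.
#'
#' @param volumes compartment volumes, m^3.
#' @param interfaces data frame with one row per interface: integer columns
#'   `from`, `to` (compartment indices, 0 for an external reservoir — at most
#'   one side), numeric `area` (m^2), `Gw` (hydraulic conductance per unit
#'   area, m s^-1 Pa^-1), `dz` (centre-to-centre elevation gain from `from`
#'   to `to`, m; 0 for radial interfaces), character `btype` (`"none"`,
#'   `"soil"`, `"open_top"`), numeric `bP` (reservoir pressure, Pa; NA for
#'   interior), `poisson_d` (centre distance for the potential solve, m; NA
#'   excludes the face from the Poisson stencil).
#' @param k matrix (interface x species) of solute permeabilities, m s^-1.
#' @param sigma matrix (interface x species) of reflection coefficients.
#' @param ions ion roster tibble (valences and reservoir concentrations).
#' @param constants [physical_constants()].
#' @param potential_mode `"poisson"` (finite-volume Poisson solve, grounded
#'   at the soil faces) or `"electroneutral"` (zero net charge flux into
#'   every compartment).
#' @param convection `"upwind"` (default) or `"central"` carrier
#'   concentration in the convective terms; see [root_model()].
#' @param bc optional matrix (interface x species) of reservoir
#'   concentrations for boundary rows; defaults to the roster's
#'   `soil_concentration` on `"soil"` rows.
#' @return An object of class `transport_network` with prefactorised
#'   pressure and Poisson systems.
#' @export
transport_network <- function(volumes, interfaces, k, sigma, ions,
                              constants = physical_constants(),
                              potential_mode = c("poisson", "electroneutral"),
                              convection = c("upwind", "central"),
                              bc = NULL) {
  potential_mode <- match.arg(potential_mode)
  convection <- match.arg(convection)
  check_ion_roster(ions)
  ncomp <- length(volumes)
  ni <- nrow(interfaces)
  ns <- nrow(ions)
  stopifnot(all(volumes > 0), is.matrix(k), is.matrix(sigma),
            nrow(k) == ni, nrow(sigma) == ni, ncol(k) == ns, ncol(sigma) == ns)
  fr <- as.integer(interfaces$from)
  to <- as.integer(interfaces$to)
  if (any(fr == 0L & to == 0L) || any(fr < 0L) || any(to < 0L) ||
      any(fr > ncomp) || any(to > ncomp)) {
    stop("interface endpoints must be 0 (reservoir) or compartment indices",
         call. = FALSE)
  }
  if (any(interfaces$area <= 0)) stop("interface areas must be positive", call. = FALSE)
  if (any(interfaces$Gw < 0)) stop("hydraulic conductances must be non-negative", call. = FALSE)
  if (any(k < 0)) stop("solute permeabilities must be non-negative", call. = FALSE)
  sigma <- clamp01(sigma)
  btype <- as.character(interfaces$btype)
  is_bound <- btype != "none"
  if (any(is_bound != (fr == 0L | to == 0L))) {
    stop("boundary rows must have btype 'soil' or 'open_top'", call. = FALSE)
  }

  if (is.null(bc)) {
    bc <- matrix(NA_real_, ni, ns)
    soil_rows <- which(btype == "soil")
    if (length(soil_rows)) {
      bc[soil_rows, ] <- matrix(ions$soil_concentration, length(soil_rows), ns,
                                byrow = TRUE)
    }
  }

  W <- interfaces$area * interfaces$Gw

  # pressure system: K P = -c(q); assemble the constant coefficient matrix K
  # from Jv_e = Gw_e * (P_from - P_to - q_e) and per-compartment volume balance
  ii <- jj <- integer(0); xx <- numeric(0)
  add <- function(i, j, x) {
    ii <<- c(ii, i); jj <<- c(jj, j); xx <<- c(xx, x)
  }
  int_e <- which(fr > 0L & to > 0L)
  if (length(int_e)) {
    a <- fr[int_e]; b <- to[int_e]; w <- W[int_e]
    add(b, a, w); add(b, b, -w); add(a, a, -w); add(a, b, w)
  }
  from0 <- which(fr == 0L)     # reservoir on the 'from' side
  if (length(from0)) add(to[from0], to[from0], -W[from0])
  to0 <- which(to == 0L)       # reservoir on the 'to' side
  if (length(to0)) add(fr[to0], fr[to0], -W[to0])
  K <- Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(ncomp, ncomp))
  dead <- which(Matrix::rowSums(abs(K)) == 0)
  if (length(dead)) {
    stop("pressure system is singular: compartment(s) ",
         paste(dead, collapse = ", "),
         " are hydraulically disconnected", call. = FALSE)
  }
  pinned <- FALSE
  if (length(from0) + length(to0) == 0L) {
    # closed network: pressure defined up to a constant; pin compartment 1
    pinned <- TRUE
    K[1, ] <- 0; K[1, 1] <- -1
  }
  Kn <- -K  # symmetric positive definite (weighted Laplacian + boundary terms)
  pressure_chol <- tryCatch(Matrix::Cholesky(Matrix::forceSymmetric(Kn), LDL = FALSE),
                            error = function(e) NULL)
  pressure_lu <- if (is.null(pressure_chol)) Matrix::lu(Kn) else NULL
  if (is.null(pressure_chol) && is.null(pressure_lu)) {
    stop("pressure system is singular: a compartment is hydraulically disconnected",
         call. = FALSE)
  }

  # Poisson system (finite volume): Lpsi psi = (F / (eps0 eps_r)) * q * V,
  # Dirichlet psi = 0 on soil faces, Neumann elsewhere
  pd <- interfaces$poisson_d
  pe <- which(!is.na(pd) & pd > 0)
  poisson_chol <- NULL
  if (length(pe)) {
    g <- interfaces$area[pe] / pd[pe]
    ii <- jj <- integer(0); xx <- numeric(0)
    pint <- pe[fr[pe] > 0L & to[pe] > 0L]
    if (length(pint)) {
      gi <- interfaces$area[pint] / pd[pint]
      a <- fr[pint]; b <- to[pint]
      add2 <- function(i, j, x) { ii <<- c(ii, i); jj <<- c(jj, j); xx <<- c(xx, x) }
      add2(a, a, gi); add2(b, b, gi); add2(a, b, -gi); add2(b, a, -gi)
    }
    pbnd <- pe[fr[pe] == 0L | to[pe] == 0L]
    if (length(pbnd)) {
      gb <- interfaces$area[pbnd] / pd[pbnd]
      cb <- pmax(fr[pbnd], to[pbnd])
      ii <- c(ii, cb); jj <- c(jj, cb); xx <- c(xx, gb)
    }
    Lpsi <- Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(ncomp, ncomp))
    poisson_chol <- tryCatch(Matrix::Cholesky(Matrix::forceSymmetric(Lpsi), LDL = FALSE,
                                              perm = TRUE),
                             error = function(e) NULL)
    if (is.null(poisson_chol)) {
      # no Dirichlet face anywhere: pin compartment 1 to 0 V
      Lpsi[1, 1] <- Lpsi[1, 1] + 1
      poisson_chol <- Matrix::Cholesky(Matrix::forceSymmetric(Lpsi), LDL = FALSE)
    }
  }
  if (potential_mode == "poisson" && is.null(poisson_chol)) {
    stop("potential_mode 'poisson' requires poisson_d on at least one face",
         call. = FALSE)
  }

  # divergence operator: net interface inflow per compartment
  di <- dj <- integer(0); dx <- numeric(0)
  keep <- to > 0L
  di <- c(di, to[keep]); dj <- c(dj, which(keep)); dx <- c(dx, rep(1, sum(keep)))
  keep <- fr > 0L
  di <- c(di, fr[keep]); dj <- c(dj, which(keep)); dx <- c(dx, rep(-1, sum(keep)))
  Din <- Matrix::sparseMatrix(i = di, j = dj, x = dx, dims = c(ncomp, ni))

  # total interface area per compartment (steady-state norm scale)
  A_comp <- as.vector(abs(Din) %*% interfaces$area)

  structure(list(
    volumes = as.numeric(volumes), ncomp = ncomp, ni = ni, ns = ns,
    from = fr, to = to, area = interfaces$area, Gw = interfaces$Gw,
    dz = interfaces$dz, btype = btype, bP = interfaces$bP,
    poisson_d = pd, k = k, sigma = sigma, bc = bc,
    ions = ions, z = ions$valence, constants = constants,
    potential_mode = potential_mode, convection = convection,
    W = W, pressure_chol = pressure_chol, pressure_lu = pressure_lu,
    pressure_pinned = pinned,
    poisson_chol = poisson_chol, Din = Din, A_comp = A_comp,
    int_e = int_e, from0 = from0, to0 = to0,
    soil_rows = which(btype == "soil"), top_rows = which(btype == "open_top")
  ), class = "transport_network")
}

# concentrations on the two sides of every interface; boundary sides use the
# reservoir concentration ("soil") or mirror the interior value ("open_top",
# no concentration gradient)
interface_concentrations <- function(net, cmat) {
  ca <- matrix(0, net$ni, net$ns)
  cb <- ca
  ia <- net$from > 0L
  ca[ia, ] <- cmat[net$from[ia], , drop = FALSE]
  ib <- net$to > 0L
  cb[ib, ] <- cmat[net$to[ib], , drop = FALSE]
  if (length(net$soil_rows)) {
    sr <- net$soil_rows
    onfrom <- net$from[sr] == 0L
    ca[sr[onfrom], ] <- net$bc[sr[onfrom], , drop = FALSE]
    cb[sr[!onfrom], ] <- net$bc[sr[!onfrom], , drop = FALSE]
  }
  if (length(net$top_rows)) {
    tr <- net$top_rows
    onto <- net$to[tr] == 0L
    cb[tr[onto], ] <- ca[tr[onto], , drop = FALSE]
    ca[tr[!onto], ] <- cb[tr[!onto], , drop = FALSE]
  }
  list(ca = ca, cb = cb)
}

# per-interface weights of the two sides in the convective carrier
# concentration: upwind takes the upstream compartment, central the
# arithmetic mean (unstable where (1 - sigma) * |Jv| / k exceeds ~2)
convection_weights <- function(net, Jv) {
  if (identical(net$convection, "central")) {
    wa <- rep(0.5, net$ni)
  } else {
    wa <- as.numeric(Jv >= 0)
  }
  list(wa = wa, wb = 1 - wa)
}

# osmotic + gravity driving term q_e of Jv_e = Gw_e (P_from - P_to - q_e)
interface_q <- function(net, ca, cb) {
  cst <- net$constants
  net$constants$rho * cst$g * net$dz +
    cst$R * cst$T * rowSums(net$sigma * (ca - cb))
}

solve_pressure_core <- function(net, q) {
  # volume balance per compartment is K P + const = 0 with the constant part
  # collecting the q_e terms and the known reservoir pressures; the solve is
  # (-K) P = const against the prefactorised SPD matrix
  cvec <- numeric(net$ncomp)
  Wq <- net$W * q
  if (length(net$int_e)) {
    e <- net$int_e
    cvec <- cvec + tab_sum(net$to[e], -Wq[e], net$ncomp) +
      tab_sum(net$from[e], Wq[e], net$ncomp)
  }
  if (length(net$from0)) {
    e <- net$from0
    cvec <- cvec + tab_sum(net$to[e], net$W[e] * (net$bP[e] - q[e]), net$ncomp)
  }
  if (length(net$to0)) {
    e <- net$to0
    cvec <- cvec + tab_sum(net$from[e], net$W[e] * (net$bP[e] + q[e]), net$ncomp)
  }
  if (net$pressure_pinned) cvec[1] <- 0  # gauge: P[1] = 0
  if (!is.null(net$pressure_chol)) {
    as.numeric(Matrix::solve(net$pressure_chol, cvec))
  } else {
    as.numeric(Matrix::solve(net$pressure_lu, cvec))
  }
}

# accumulate contributions per compartment index
tab_sum <- function(idx, val, n) {
  out <- numeric(n)
  agg <- rowsum(val, idx)
  out[as.integer(rownames(agg))] <- agg[, 1]
  out
}

interface_pressures <- function(net, P) {
  Pa <- numeric(net$ni); Pb <- numeric(net$ni)
  ia <- net$from > 0L
  Pa[ia] <- P[net$from[ia]]
  Pa[!ia] <- net$bP[!ia]
  ib <- net$to > 0L
  Pb[ib] <- P[net$to[ib]]
  Pb[!ib] <- net$bP[!ib]
  list(Pa = Pa, Pb = Pb)
}

# electroneutral (zero-current) linear system: returns the conductance
# matrix K and constant vector cvec such that K psi + cvec = 0 expresses
# zero net charge flux into every compartment, plus the per-interface
# ingredients (gamma, s)
electroneutral_system <- function(net, ca, cb, Jv) {
  cst <- net$constants
  cbar <- pmax((ca + cb) / 2, 0)
  cconv <- cbar
  if (!is.null(Jv)) {
    w <- convection_weights(net, Jv)
    cconv <- pmax(w$wa * ca + w$wb * cb, 0)
  }
  zmat <- matrix(net$z, net$ni, net$ns, byrow = TRUE)
  # the zero-current system becomes ill-conditioned while compartments are
  # nearly carrier-free (e.g. a root filling from empty); a background
  # carrier concentration of 0.1% of the reservoir level bounds the
  # potential response without influencing fluxes (the potential multiplies
  # the true, unfloored concentrations)
  c_floor <- 1e-3 * max(net$ions$soil_concentration, 1)
  gamma <- rowSums(net$k * zmat^2 * pmax(cbar, c_floor)) *
    (cst$F / (cst$R * cst$T))
  # non-electric per-area charge flux on each interface
  s <- rowSums(zmat * (net$k * (ca - cb)))
  if (!is.null(Jv)) {
    s <- s + rowSums(zmat * ((1 - net$sigma) * cconv)) * Jv
  }
  if (length(net$top_rows)) {
    tr <- net$top_rows
    s[tr] <- as.numeric((cb[tr, , drop = FALSE] %*% net$z)) * Jv[tr]
    gamma[tr] <- 0  # purely convective: no potential coupling at the open top
  }
  Ag <- net$area * gamma
  As <- net$area * s
  ii <- jj <- integer(0); xx <- numeric(0)
  fr <- net$from; to <- net$to
  int_e <- net$int_e
  if (length(int_e)) {
    a <- fr[int_e]; b <- to[int_e]; w <- Ag[int_e]
    ii <- c(ii, b, b, a, a); jj <- c(jj, a, b, a, b); xx <- c(xx, w, -w, -w, w)
  }
  cvec <- numeric(net$ncomp)
  if (length(int_e)) {
    cvec <- cvec + tab_sum(to[int_e], As[int_e], net$ncomp) -
      tab_sum(fr[int_e], As[int_e], net$ncomp)
  }
  bnd <- which(net$btype != "none")
  for (e in bnd) {
    comp <- max(fr[e], to[e])
    sgn <- if (net$to[e] == comp) 1 else -1
    # reservoir potential is 0 on soil faces; open-top faces have gamma = 0
    ii <- c(ii, comp); jj <- c(jj, comp); xx <- c(xx, -Ag[e])
    cvec[comp] <- cvec[comp] + sgn * As[e]
  }
  if (all(Ag == 0)) {
    return(list(K = NULL, cvec = cvec, gamma = gamma, s = s))
  }
  # compartments without carriers have zero-conductance rows; a small
  # diagonal leak (1e-10 of the largest conductance) pins their potential to
  # the ground value without affecting carrier-rich compartments
  reg <- 1e-8 * max(Ag)
  Kpsi <- Matrix::sparseMatrix(i = ii, j = jj, x = xx,
                               dims = c(net$ncomp, net$ncomp)) -
    Matrix::Diagonal(net$ncomp, reg)
  if (!any(net$btype == "soil")) {
    Kpsi[1, ] <- 0; Kpsi[1, 1] <- -1; cvec[1] <- 0
  }
  list(K = Kpsi, cvec = cvec, gamma = gamma, s = s)
}

solve_potential_core <- function(net, cmat, ca, cb, Jv = NULL, q = NULL) {
  cst <- net$constants
  if (net$potential_mode == "poisson") {
    charge <- as.numeric(cmat %*% net$z)               # mol m^-3
    src <- (cst$F / (cst$eps0 * cst$eps_r)) * charge * net$volumes
    psi <- as.numeric(Matrix::solve(net$poisson_chol, src))
    return(psi)
  }
  sys <- electroneutral_system(net, ca, cb, Jv)
  if (is.null(sys$K)) return(numeric(net$ncomp))  # no charge carriers anywhere
  as.numeric(Matrix::solve(sys$K, -sys$cvec))
}

# all interface fluxes for a given concentration state; returns Jv and the
# per-species decomposition (diffusive, electric, convective)
network_fluxes <- function(net, cmat, psi = NULL, P = NULL) {
  cc <- interface_concentrations(net, cmat)
  q <- interface_q(net, cc$ca, cc$cb)
  if (is.null(P)) P <- solve_pressure_core(net, q)
  pp <- interface_pressures(net, P)
  Jv <- net$Gw * (pp$Pa - pp$Pb - q)
  if (is.null(psi)) {
    psi <- solve_potential_core(net, cmat, cc$ca, cc$cb, Jv = Jv, q = q)
  }
  cst <- net$constants
  psia <- numeric(net$ni); psib <- numeric(net$ni)
  ia <- net$from > 0L
  psia[ia] <- psi[net$from[ia]]           # reservoir faces sit at 0 V
  ib <- net$to > 0L
  psib[ib] <- psi[net$to[ib]]
  if (length(net$top_rows)) {             # no-gradient outflow: no field jump
    tr <- net$top_rows
    psia[tr] <- 0; psib[tr] <- 0
  }
  dpsi <- psia - psib
  # the interface mean concentration is floored at zero in the carrier
  # terms: transient undershoots below zero would otherwise feed back
  # through the osmotic coupling and destabilise the integration (at
  # physical states the floor is inactive)
  cbar <- pmax((cc$ca + cc$cb) / 2, 0)
  w <- convection_weights(net, Jv)
  cconv <- pmax(w$wa * cc$ca + w$wb * cc$cb, 0)
  zmat <- matrix(net$z, net$ni, net$ns, byrow = TRUE)
  J_diff <- net$k * (cc$ca - cc$cb)
  J_elec <- net$k * zmat * (cst$F / (cst$R * cst$T)) * cbar * dpsi
  J_conv <- (1 - net$sigma) * cconv * Jv
  list(Jv = Jv, J_diff = J_diff, J_elec = J_elec, J_conv = J_conv,
       J_total = J_diff + J_elec + J_conv, P = P, psi = psi, q = q)
}

# time derivative of the concentration state (mol m^-3 s^-1), plus the field
# snapshot used to compute it
network_rhs <- function(net, cmat, want_fields = FALSE) {
  fl <- network_fluxes(net, cmat)
  dC <- as.matrix(net$Din %*% (net$area * fl$J_total)) / net$volumes
  if (want_fields) list(dC = dC, fields = fl) else list(dC = dC)
}

# steady-state norm: net mole rate per compartment relative to its own
# membrane-exchange capacity k_ref * c_ref * A_comp
steady_norm <- function(net, dC, species = NULL, k_ref = 3e-9, c_ref = NULL) {
  if (is.null(c_ref)) c_ref <- max(net$ions$soil_concentration, 1)
  if (!is.null(species)) dC <- dC[, species, drop = FALSE]
  max(abs(dC) * net$volumes / (k_ref * c_ref * net$A_comp))
}

# pressure-solve residual: max net volume inflow relative to the dominant
# interface volume flow; the scale is floored at the flow a 1 Pa drop would
# drive through the most conductive interface, so an all-zero-flux
# equilibrium reports ~0 rather than 0/0 noise
pressure_residual <- function(net, Jv) {
  div <- as.numeric(net$Din %*% (net$area * Jv))
  scale <- max(abs(net$area * Jv), max(net$W) * 1)
  max(abs(div)) / scale
}
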