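#' Baseline transport parameters
#'
#' Baseline interface parameters of the composite (apoplast + symplast)
#' tissue: the root hydraulic conductivity, solute diffusive permeability and
#' reflection coefficient apply to every membrane interface, radial and
#' axial, unless a barrier or xylem-maturation rule modifies them. The mature
#' xylem lumen has no axial membranes: its axial water flow is Darcy flow
#' with permeability `k_ax_channel` and its axial solute transport is free
#' diffusion with coefficient `D_free` (zero reflection).
#'
#' `Lp` is accepted in the conventional m s^-1 MPa^-1 and converted to SI
#' (m s^-1 Pa^-1) once, at construction.
#'
#' @param Lp membrane water permeability, m s^-1 MPa^-1.
#' @param k membrane solute diffusive permeability, m s^-1.
#' @param sigma membrane reflection coefficient, dimensionless in \[0,1\].
#' @param Lp_axial axial membrane water permeability for non-xylem tissues
#'   and immature xylem, m s^-1 MPa^-1 (defaults to the radial baseline).
#' @param k_axial axial membrane solute permeability, m s^-1.
#' @param sigma_axial axial membrane reflection coefficient.
#' @param k_ax_channel Darcy permeability of the mature xylem lumen, m^2.
#' @param D_free free-solution diffusion coefficient used for axial solute
#'   transport in the mature xylem, m^2 s^-1.
#' @return A list of validated baseline parameters with `Lp`/`Lp_axial`
#'   stored in SI units (m s^-1 Pa^-1).
#' @export
transport_defaults <- function(Lp = 5.5e-8, k = 3e-9, sigma = 0.5,
                               Lp_axial = Lp, k_axial = k,
                               sigma_axial = sigma,
                               k_ax_channel = 5e-13, D_free = 1.5e-9) {
  if (Lp < 0 || Lp_axial < 0 || k < 0 || k_axial < 0) {
    stop("permeabilities must be non-negative", call. = FALSE)
  }
  if (k_ax_channel <= 0 || D_free <= 0) {
    stop("xylem channel permeability and D_free must be positive", call. = FALSE)
  }
  list(Lp = Lp * 1e-6,            # m/s/MPa -> m/s/Pa
       k = k,
       sigma = clamp01(sigma),
       Lp_axial = Lp_axial * 1e-6,
       k_axial = k_axial,
       sigma_axial = clamp01(sigma_axial),
       k_ax_channel = k_ax_channel,
       D_free = D_free)
}

clamp01 <- function(x) pmin(pmax(x, 0), 1)

#' Describe an endodermal-barrier scenario
#'
#' The four barrier topologies: `"A"` no endodermal barriers, `"B"` Casparian
#' strip (CS) only, `"C"` CS plus a solid, uninterrupted suberin lamellae
#' (SL) barrier, `"D"` CS plus SL with randomly placed passage cells. Each
#' barrier divides the radial diffusive and water permeabilities at the
#' endodermis-pericycle interface by `cs_factor` (an order of magnitude by
#' default) and adds `sigma_increment` to the radial reflection coefficient.
#'
#' @param scenario_id one of `"A"`, `"B"`, `"C"`, `"D"`.
#' @param cs_factor per-barrier reduction factor on permeabilities (> 1).
#' @param sigma_increment per-barrier additive increase of the reflection
#'   coefficient (0 < increment <= 0.5).
#' @param seed integer seed for passage-cell sampling (scenario D).
#' @param passage_decay scale of the passage-cell probability exp(-j /
#'   passage_decay).
#' @return An object of class `barrier_scenario`.
#' @export
#' @examples
#' barrier_scenario("D", seed = 1)
barrier_scenario <- function(scenario_id = c("A", "B", "C", "D"),
                             cs_factor = 10, sigma_increment = 0.2,
                             seed = 1L, passage_decay = 30) {
  scenario_id <- match.arg(scenario_id)
  if (cs_factor <= 1) stop("cs_factor must exceed 1", call. = FALSE)
  if (sigma_increment <= 0 || sigma_increment > 0.5) {
    stop("sigma_increment must lie in (0, 0.5]", call. = FALSE)
  }
  if (passage_decay <= 0) stop("passage_decay must be positive", call. = FALSE)
  structure(list(scenario_id = scenario_id, cs_factor = cs_factor,
                 sigma_increment = sigma_increment,
                 seed = as.integer(seed), passage_decay = passage_decay),
            class = "barrier_scenario")
}

#' Sample passage-cell locations
#'
#' From `sl_start` upward, each endodermal cell is independently a passage
#' cell (SL absent, CS still present) with probability
#' `exp(-j / passage_decay)` where `j` counts cells from the start of the EZ,
#' mirroring the observed decline of passage cells with root maturity. The
#' draw is reproducible for a given seed and leaves the caller's RNG state
#' untouched.
#'
#' @param zone_map a [build_zone_map()] object.
#' @param seed integer seed.
#' @param passage_decay probability scale (cells).
#' @return An object of class `passage_cell_mask`: list with integer vector
#'   `j` (cells from `sl_start` to `n_axial`), logical `passage`, and the
#'   `seed` used. Empty when `sl_start > n_axial`.
#' @export
#' @examples
#' zm <- build_zone_map(build_geometry(geometry_config(n_axial = 60)))
#' m <- sample_passage_cells(zm, seed = 7)
#' sum(m$passage)
sample_passage_cells <- function(zone_map, seed, passage_decay = 30) {
  stopifnot(inherits(zone_map, "zone_map"))
  if (missing(seed) || is.null(seed)) stop("seed is required", call. = FALSE)
  if (passage_decay <= 0) stop("passage_decay must be positive", call. = FALSE)
  j <- seq.int(zone_map$sl_start, length.out =
                 max(0L, zone_map$n_axial - zone_map$sl_start + 1L))
  passage <- logical(length(j))
  if (length(j) > 0) {
    old <- if (exists(".Random.seed", envir = globalenv())) {
      get(".Random.seed", envir = globalenv())
    }
    on.exit({
      if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    }, add = TRUE)
    set.seed(as.integer(seed))
    passage <- stats::runif(length(j)) < exp(-j / passage_decay)
  }
  structure(list(j = j, passage = passage, seed = as.integer(seed),
                 passage_decay = passage_decay),
            class = "passage_cell_mask")
}

#' @export
print.passage_cell_mask <- function(x, ...) {
  cat(sprintf("Passage-cell mask (seed %d): %d passage cells among cells %s\n",
              x$seed, sum(x$passage),
              if (length(x$j)) paste0(min(x$j), "-", max(x$j)) else "<none>"))
  invisible(x)
}

#' Assign transport parameters to every compartment interface
#'
#' Lays the baseline membrane parameters over every radial and axial
#' interface, then applies the developmental rules:
#' \itemize{
#' \item Casparian strip and suberin lamellae modify only the
#'   endodermis-pericycle interface. Where the CS development weight `w` is
#'   positive, `k` and `Lp` are divided by `cs_factor^w` and `sigma` is
#'   raised by `sigma_increment * w` (permeabilities interpolate
#'   geometrically across the ramp, the reflection coefficient
#'   arithmetically). Where the SL applies (cells at or above `sl_start`
#'   that are not passage cells, scenarios C and D) a second full factor and
#'   increment are applied.
#' \item Xylem axial interfaces turn from membrane-type into open Darcy
#'   channels across the xylem development ramp: hydraulic and diffusive
#'   conductances interpolate geometrically between the membrane values and
#'   the open-channel values `k_ax_channel / (mu * dz)` and `D_free / dz`,
#'   and the axial reflection coefficient scales as `sigma * (1 - w)`.
#' }
#' Reflection coefficients are clamped to \[0, 1\].
#'
#' @param geometry a [build_geometry()] object.
#' @param zone_map a [build_zone_map()] object.
#' @param scenario a [barrier_scenario()].
#' @param ions ion roster tibble (see [default_ions()]).
#' @param base baseline parameters from [transport_defaults()].
#' @param mask optional pre-sampled [sample_passage_cells()] mask (scenario D);
#'   sampled from `scenario$seed` when absent.
#' @return An object of class `parameter_field`: arrays
#'   `radial_Lp` (boundary x j, SI), `radial_k`, `radial_sigma`
#'   (boundary x j x species), `axial_Lp` (layer x j-interface),
#'   `axial_k`, `axial_sigma`, `w_open` (xylem-channel weight per axial
#'   interface), plus the mask and scenario metadata.
#' @export
assign_parameters <- function(geometry, zone_map, scenario = barrier_scenario("D"),
                              ions = default_ions(), base = transport_defaults(),
                              mask = NULL) {
  stopifnot(inherits(geometry, "root_geometry"), inherits(zone_map, "zone_map"),
            inherits(scenario, "barrier_scenario"))
  check_ion_roster(ions)
  n <- geometry$n_axial
  ns <- nrow(ions)
  nb <- 5L

  kscale <- ions$permeability_scale

  radial_Lp <- matrix(base$Lp, nb, n, dimnames = list(.boundary_names, NULL))
  radial_k <- array(rep(base$k * kscale, each = nb * n), dim = c(nb, n, ns),
                    dimnames = list(.boundary_names, NULL, ions$name))
  radial_sigma <- array(base$sigma, dim = c(nb, n, ns),
                        dimnames = list(.boundary_names, NULL, ions$name))

  # barrier weights per cell: CS ramp weight + a full unit where SL applies
  w_cs <- zone_map$w_cs
  sl <- rep(FALSE, n)
  if (scenario$scenario_id %in% c("C", "D") &&
      zone_map$sl_start <= n) {
    sl[zone_map$sl_start:n] <- TRUE
    if (scenario$scenario_id == "D") {
      if (is.null(mask)) {
        mask <- sample_passage_cells(zone_map, scenario$seed,
                                     scenario$passage_decay)
      }
      sl[mask$j[mask$passage]] <- FALSE
    }
  }
  if (scenario$scenario_id == "A") w_cs <- rep(0, n)
  w_barrier <- w_cs + as.numeric(sl)

  bi <- 4L  # endodermis|pericycle boundary
  radial_Lp[bi, ] <- radial_Lp[bi, ] / scenario$cs_factor^w_barrier
  for (i in seq_len(ns)) {
    radial_k[bi, , i] <- radial_k[bi, , i] / scenario$cs_factor^w_barrier
    radial_sigma[bi, , i] <- clamp01(radial_sigma[bi, , i] +
                                       scenario$sigma_increment * w_barrier)
  }

  # axial interfaces: one between each pair of vertically adjacent cells
  na <- max(0L, n - 1L)
  axial_Lp <- matrix(base$Lp_axial, 5L, na, dimnames = list(.layer_names, NULL))
  axial_k <- array(rep(base$k_axial * kscale, each = 5L * na),
                   dim = c(5L, na, ns),
                   dimnames = list(.layer_names, NULL, ions$name))
  axial_sigma <- array(base$sigma_axial, dim = c(5L, na, ns),
                       dimnames = list(.layer_names, NULL, ions$name))
  w_open <- matrix(0, 5L, na, dimnames = list(.layer_names, NULL))
  if (na > 0L) {
    # the interface between cells j and j+1 carries the development weight of
    # the lower cell j (weights are non-decreasing in j)
    w_open["xylem", ] <- zone_map$w_xylem[seq_len(na)]
  }
  # xylem top: weight of the top cell
  w_top <- zone_map$w_xylem[n]

  structure(list(radial_Lp = radial_Lp, radial_k = radial_k,
                 radial_sigma = radial_sigma,
                 axial_Lp = axial_Lp, axial_k = axial_k,
                 axial_sigma = axial_sigma,
                 w_open = w_open, w_open_top = w_top,
                 base = base, scenario = scenario, mask = mask,
                 sl_cells = sl, w_barrier = w_barrier,
                 ions = ions),
            class = "parameter_field")
}

#' @export
print.parameter_field <- function(x, ...) {
  cat(sprintf("Parameter field: scenario %s (cs_factor %.3g, sigma +%.2g/barrier)\n",
              x$scenario$scenario_id, x$scenario$cs_factor,
              x$scenario$sigma_increment))
  if (!is.null(x$mask)) print(x$mask)
  invisible(x)
}

#' Tabulate interface parameters
#'
#' One row per radial interface with its effective permeability, reflection
#' coefficient and water permeability — the plain-text parameter dump.
#'
#' @param params a [assign_parameters()] object.
#' @return A tibble with one row per (boundary, axial cell) interface.
#' @export
parameter_table <- function(params) {
  stopifnot(inherits(params, "parameter_field"))
  nb <- nrow(params$radial_Lp)
  n <- ncol(params$radial_Lp)
  tibble::tibble(
    boundary = rep(rownames(params$radial_Lp), times = n),
    j = rep(seq_len(n), each = nb),
    Lp = as.vector(params$radial_Lp),
    k = as.vector(params$radial_k[, , 1L]),
    sigma = as.vector(params$radial_sigma[, , 1L])
  )
}
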