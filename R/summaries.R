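#' Axial zone definitions used by the summary statistics
#'
#' Zones along the root: `EZ` (cells up to the end of the height ramp),
#' `cs_developing` (cells from `cs_start` until the CS reaches full
#' strength), `cs_mature` (full CS, below `sl_start`), `sl_mature` (cells at
#' or above `sl_start` with SL present) and `passage` (passage cells).
#'
#' @param zone_map a [build_zone_map()] object.
#' @param mask optional [sample_passage_cells()] mask (needed for the
#'   `sl_mature` / `passage` split).
#' @return Named list of integer axial-index vectors (possibly empty).
#' @export
summary_zones <- function(zone_map, mask = NULL) {
  n <- zone_map$n_axial
  j <- seq_len(n)
  cs_dev <- j[zone_map$w_cs > 0 & zone_map$w_cs < 1]
  cs_full <- j[zone_map$w_cs >= 1]
  sl_region <- if (zone_map$sl_start <= n) zone_map$sl_start:n else integer(0)
  passage <- if (!is.null(mask)) mask$j[mask$passage] else integer(0)
  list(EZ = j[j <= zone_map$ez_end],
       cs_developing = cs_dev,
       cs_mature = setdiff(cs_full, sl_region),
       sl_mature = setdiff(sl_region, passage),
       passage = passage)
}

#' Zone-averaged net radial ion flux across the root surface
#'
#' Area-weighted mean, over the zone's axial cells, of the total (all
#' species) ion flux through the soil-epidermis interface; positive = uptake.
#'
#' @param steady a [integrate_to_steady_state()] result for a [root_model()].
#' @param zone one of `"EZ"`, `"cs_developing"`, `"cs_mature"`,
#'   `"sl_mature"`, `"passage"`, or an integer vector of axial cells.
#' @param mask optional passage-cell mask; defaults to the model's.
#' @return Flux in mol s^-1 m^-2 (`NA` with a warning for an empty zone).
#' @export
zone_average_radial_flux <- function(steady, zone, mask = NULL) {
  model <- steady$model
  stopifnot(inherits(model, "root_model"))
  if (is.null(mask)) mask <- model$params$mask
  cells <- if (is.numeric(zone)) {
    as.integer(zone)
  } else {
    zones <- summary_zones(model$zone_map, mask)
    if (!zone %in% names(zones)) {
      stop("unknown zone '", zone, "'", call. = FALSE)
    }
    zones[[zone]]
  }
  if (length(cells) == 0) {
    warning("zone has no axial cells; returning NA", call. = FALSE)
    return(NA_real_)
  }
  rows <- model$soil_iface[cells]
  f <- rowSums(steady$fluxes$J_total[rows, , drop = FALSE])  # mol m^-2 s^-1
  a <- model$network$area[rows]
  sum(f * a) / sum(a)
}

#' Summary table of zone-averaged surface fluxes
#'
#' @param steady a steady-state result for a [root_model()].
#' @return A tibble with columns `zone`, `n_cells`, `flux_mol_m2_s`,
#'   `flux_nmol_m2_s`.
#' @export
zone_flux_table <- function(steady) {
  model <- steady$model
  zones <- summary_zones(model$zone_map, model$params$mask)
  tibble::tibble(
    zone = names(zones),
    n_cells = vapply(zones, length, integer(1)),
    flux_mol_m2_s = vapply(names(zones), function(z) {
      if (length(zones[[z]]) == 0) NA_real_
      else zone_average_radial_flux(steady, z)
    }, numeric(1))
  ) -> tab
  tab$flux_nmol_m2_s <- tab$flux_mol_m2_s * 1e9
  tab
}

#' Axial ion and water efflux near the top of the xylem
#'
#' Total upward ion flux (mol s^-1, all species) and water flow (m^3 s^-1)
#' through the xylem's axial interface three cells below the top of the root
#' — far enough from the top boundary to be insensitive to its flux
#' condition.
#'
#' @param steady a steady-state result for a [root_model()].
#' @param cells_below how many cells below the top to measure (default 3).
#' @return A list with `ion_flux_mol_s` and `water_flow_m3_s`.
#' @export
xylem_top_efflux <- function(steady, cells_below = 3L) {
  model <- steady$model
  stopifnot(inherits(model, "root_model"))
  n <- model$n_axial
  if (n < cells_below + 1L) {
    stop("root too short: need n_axial >= ", cells_below + 1L, call. = FALSE)
  }
  # axial interface between cells (n - cells_below) and (n - cells_below + 1)
  row <- model$axial_iface[n - cells_below, 5L]
  a <- model$network$area[row]
  list(ion_flux_mol_s = sum(steady$fluxes$J_total[row, ]) * a,
       water_flow_m3_s = steady$fluxes$Jv[row] * a)
}

#' Per-tissue axial concentration profiles
#'
#' @param steady a steady-state result (or any state snapshot with a model).
#' @param tissues layer names to report (default xylem, pericycle,
#'   endodermis).
#' @param state optional concentration matrix overriding the steady state.
#' @return A tibble with columns `layer`, `j`, `zone`, `species`,
#'   `concentration` (mol m^-3).
#' @export
concentration_profiles <- function(steady,
                                   tissues = c("xylem", "pericycle", "endodermis"),
                                   state = NULL) {
  model <- steady$model
  stopifnot(inherits(model, "root_model"))
  cmat <- if (is.null(state)) steady$state else state
  n <- model$n_axial
  lnames <- .layer_names
  out <- list()
  for (tis in tissues) {
    l <- match(tis, lnames)
    if (is.na(l)) stop("unknown tissue '", tis, "'", call. = FALSE)
    rows <- model$comp_index(l, seq_len(n))
    for (s in seq_len(model$ns)) {
      out[[length(out) + 1L]] <- tibble::tibble(
        layer = tis, j = seq_len(n),
        zone = as.character(model$zone_map$zone),
        species = model$ions$name[s],
        concentration = cmat[rows, s])
    }
  }
  do.call(rbind, out)
}

#' Sign of the axial concentration trend in the mature-DZ xylem
#'
#' Fits the slope of the xylem concentration (first species) against axial
#' index over the mature DZ segment (cells where both the CS and xylem are
#' fully developed, excluding the top three cells next to the outflow
#' boundary). Returns +1 for increasing with height, -1 for decreasing.
#'
#' @param steady a steady-state result.
#' @return A list with `slope` (mol m^-3 per cell), `sign`, and the logical
#'   `monotone` (strict monotonicity of the segment).
#' @export
xylem_axial_trend <- function(steady) {
  model <- steady$model
  zm <- model$zone_map
  n <- model$n_axial
  jmin <- max(which(zm$w_cs >= 1 & zm$w_xylem >= 1)[1], 1L)
  cells <- seq.int(jmin, max(jmin + 1L, n - 3L))
  prof <- steady$state[model$comp_index(5L, cells), 1L]
  slope <- unname(stats::coef(stats::lm(prof ~ cells))[2])
  d <- diff(prof)
  list(slope = slope, sign = sign(slope),
       monotone = all(d > 0) || all(d < 0), cells = cells, profile = prof)
}
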