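#' Define an ion species
#'
#' An ion species is described by its name, signed valence, fixed soil (bulk)
#' concentration and an optional dimensionless multiplier on its diffusive
#' permeability (all species share the baseline membrane permeability unless
#' scaled).
#'
#' @param name species label.
#' @param valence signed integer valence; monovalent ions are +1 / -1.
#' @param soil_concentration bulk soil concentration, mol m^-3 (numerically
#'   equal to mM).
#' @param permeability_scale dimensionless multiplier on the diffusive
#'   permeability of this species.
#' @return A one-row tibble with columns `name`, `valence`,
#'   `soil_concentration`, `permeability_scale`.
#' @export
#' @examples
#' ion_species("Na", +1)
ion_species <- function(name, valence, soil_concentration = 100,
                        permeability_scale = 1) {
  if (!is.character(name) || length(name) != 1L) {
    stop("name must be a single string", call. = FALSE)
  }
  if (abs(valence) < 1 || valence != round(valence)) {
    stop("valence must be a non-zero integer", call. = FALSE)
  }
  if (soil_concentration < 0) {
    stop("soil_concentration must be non-negative", call. = FALSE)
  }
  if (permeability_scale <= 0) {
    stop("permeability_scale must be positive", call. = FALSE)
  }
  tibble::tibble(name = name, valence = as.integer(valence),
                 soil_concentration = soil_concentration,
                 permeability_scale = permeability_scale)
}

#' Default ion roster: symmetric monovalent salt pairs
#'
#' The reference soil solution holds `n_pairs` monovalent cation-anion pairs,
#' each species at the same bulk concentration (e.g. two pairs at 100 mM
#' resemble 100 mM NaCl plus 100 mM KNO3). All species share identical
#' transport properties, which keeps every compartment electroneutral and the
#' electric potential identically zero by symmetry.
#'
#' @param n_pairs number of cation-anion pairs.
#' @param soil_concentration per-species bulk concentration, mol m^-3.
#' @return A tibble with one row per species (cations first).
#' @export
#' @examples
#' default_ions()           # 2 cations + 2 anions at 100 mM each
#' default_ions(n_pairs = 1)
default_ions <- function(n_pairs = 2, soil_concentration = 100) {
  stopifnot(n_pairs >= 1)
  rows <- lapply(seq_len(n_pairs), function(p) {
    rbind(ion_species(paste0("cation", p), +1, soil_concentration),
          ion_species(paste0("anion", p), -1, soil_concentration))
  })
  out <- do.call(rbind, rows)
  # cations first, then anions, for readability of dumps
  out[order(-out$valence, out$name), ]
}

# validate a roster tibble; returns it invisibly
check_ion_roster <- function(ions) {
  need <- c("name", "valence", "soil_concentration", "permeability_scale")
  if (!all(need %in% names(ions))) {
    stop("ion roster must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (any(duplicated(ions$name))) stop("duplicate ion names", call. = FALSE)
  if (any(abs(ions$valence) < 1)) stop("|valence| must be >= 1", call. = FALSE)
  if (any(ions$soil_concentration < 0)) {
    stop("soil concentrations must be non-negative", call. = FALSE)
  }
  invisible(ions)
}
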