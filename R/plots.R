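#' Heat map of a steady-state concentration field
#'
#' Tile plot of one species' concentration over the (layer, axial cell)
#' grid, tip at the bottom.
#'
#' @param steady a steady-state result for a [root_model()].
#' @param species species name or index (default first).
#' @return A ggplot object.
#' @export
plot_concentration_map <- function(steady, species = 1L) {
  stop_without_ggplot()
  model <- steady$model
  s <- if (is.character(species)) match(species, model$ions$name) else species
  n <- model$n_axial
  df <- data.frame(
    layer = factor(rep(.layer_names, times = n), levels = rev(.layer_names)),
    j = rep(seq_len(n), each = 5L),
    concentration = steady$state[, s]
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$layer, y = .data$j,
                                   fill = .data$concentration)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(name = "c (mol m⁻³)") +
    ggplot2::labs(x = NULL, y = "axial cell (from root tip)",
                  title = sprintf("Steady-state %s concentration",
                                  model$ions$name[s])) +
    ggplot2::theme_minimal()
}

#' Axial concentration profiles per tissue
#'
#' Line plot of [concentration_profiles()] (first species) for the selected
#' tissues.
#'
#' @param steady a steady-state result.
#' @param tissues layers to draw.
#' @return A ggplot object.
#' @export
plot_concentration_profiles <- function(steady,
                                        tissues = c("xylem", "pericycle",
                                                    "endodermis")) {
  stop_without_ggplot()
  prof <- concentration_profiles(steady, tissues)
  prof <- prof[prof$species == prof$species[1], ]
  ggplot2::ggplot(prof, ggplot2::aes(x = .data$j, y = .data$concentration,
                                     colour = .data$layer)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "axial cell (from root tip)",
                  y = "concentration (mol m⁻³)", colour = "tissue") +
    ggplot2::theme_minimal()
}

#' Xylem-top efflux versus transpiration pressure
#'
#' Line plot of a [sweep_pb()] table: ion efflux near the top of the xylem
#' against the xylem-top pressure, one line per barrier scenario.
#'
#' @param sweep a [sweep_pb()] result.
#' @return A ggplot object.
#' @export
plot_pb_sweep <- function(sweep) {
  stop_without_ggplot()
  ggplot2::ggplot(sweep, ggplot2::aes(x = .data$P_b_MPa,
                                      y = .data$ion_efflux_mol_s * 1e12,
                                      colour = .data$scenario)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::scale_x_reverse() +
    ggplot2::labs(x = expression(P[b] ~ "(MPa)"),
                  y = "xylem ion efflux (pmol s⁻¹)",
                  colour = "barriers") +
    ggplot2::theme_minimal()
}

#' Net radial surface flux along the root
#'
#' Per-cell total ion flux through the root surface at steady state, with
#' the developmental landmarks marked.
#'
#' @param steady a steady-state result.
#' @return A ggplot object.
#' @export
plot_surface_flux <- function(steady) {
  stop_without_ggplot()
  model <- steady$model
  f <- rowSums(steady$fluxes$J_total[model$soil_iface, , drop = FALSE])
  df <- data.frame(j = seq_len(model$n_axial), flux = f * 1e9)
  zm <- model$zone_map
  ggplot2::ggplot(df, ggplot2::aes(x = .data$j, y = .data$flux)) +
    ggplot2::geom_col(width = 0.8) +
    ggplot2::geom_vline(xintercept = c(zm$cs_start, zm$sl_start),
                        linetype = "dashed", colour = "grey40") +
    ggplot2::labs(x = "axial cell (from root tip)",
                  y = "net radial ion flux (nmol s⁻¹ m⁻²)") +
    ggplot2::theme_minimal()
}

stop_without_ggplot <- function() {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("plotting requires the 'ggplot2' package", call. = FALSE)
  }
}
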