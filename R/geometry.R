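#' Geometry settings for the model root
#'
#' The model root is an axisymmetric right cylinder discretised radially into
#' five concentric tissue regions (outermost to innermost: epidermis, cortex,
#' endodermis, pericycle, and a solid xylem core) and axially into
#' compartments whose heights follow individual cell lengths. Cell heights
#' ramp up through the elongation zone (EZ) and are constant in the
#' differentiation zone (DZ).
#'
#' Defaults follow typical Arabidopsis primary-root dimensions: tissue
#' thicknesses 15/20/10/5 um with a 3 um xylem radius (outer root radius
#' 53 um), and an EZ height ramp from 20 um at the first cell to 150 um at
#' cell `ez_end`, constant thereafter.
#'
#' @param layer_thicknesses named numeric vector of tissue thicknesses, um,
#'   ordered outermost to innermost: epidermis, cortex, endodermis, pericycle.
#' @param xylem_radius radius of the solid xylem core, um.
#' @param n_axial number of axial compartments (cells).
#' @param ez_end index of the last elongation-zone cell (the height ramp ends
#'   here).
#' @param h_min,h_max axial cell height at the first cell and from `ez_end`
#'   onwards, um.
#' @param cell_heights optional explicit per-cell heights, um (length
#'   `n_axial`); overrides the ramp.
#' @return A list of validated geometry settings.
#' @export
geometry_config <- function(layer_thicknesses = c(epidermis = 15, cortex = 20,
                                                  endodermis = 10, pericycle = 5),
                            xylem_radius = 3,
                            n_axial = 100,
                            ez_end = 11,
                            h_min = 20,
                            h_max = 150,
                            cell_heights = NULL) {
  cfg <- list(layer_thicknesses = layer_thicknesses, xylem_radius = xylem_radius,
              n_axial = as.integer(n_axial), ez_end = as.integer(ez_end),
              h_min = h_min, h_max = h_max, cell_heights = cell_heights)
  if (length(layer_thicknesses) != 4L) {
    stop("layer_thicknesses must give the four tissue thicknesses ",
         "(epidermis, cortex, endodermis, pericycle)", call. = FALSE)
  }
  for (nm in names(layer_thicknesses)) {
    if (layer_thicknesses[[nm]] <= 0) {
      stop("layer thickness '", nm, "' must be positive", call. = FALSE)
    }
  }
  if (xylem_radius <= 0) stop("xylem_radius must be positive", call. = FALSE)
  if (cfg$n_axial < 1L) stop("n_axial must be at least 1", call. = FALSE)
  if (is.null(cell_heights)) {
    if (h_min <= 0 || h_max <= 0) {
      stop("cell heights h_min/h_max must be positive", call. = FALSE)
    }
    if (h_min > h_max) stop("h_min must not exceed h_max", call. = FALSE)
    if (cfg$ez_end < 1L) stop("ez_end must be at least 1", call. = FALSE)
  } else {
    if (length(cell_heights) != cfg$n_axial) {
      stop("cell_heights must have length n_axial", call. = FALSE)
    }
    if (any(cell_heights <= 0)) {
      stop("cell_heights must be positive", call. = FALSE)
    }
  }
  cfg
}

# canonical layer names, outermost first; the xylem is the innermost core
.layer_names <- c("epidermis", "cortex", "endodermis", "pericycle", "xylem")

# radial boundary names, outermost first (boundary b separates layer b-1 from
# layer b; boundary 1 is the root surface)
.boundary_names <- c("soil|epidermis", "epidermis|cortex", "cortex|endodermis",
                     "endodermis|pericycle", "pericycle|xylem")

#' Build the compartment grid of the model root
#'
#' Constructs the axisymmetric compartment grid: per-layer radii, per-cell
#' axial heights, compartment volumes, lateral (radial) interface areas and
#' horizontal (axial) interface areas. Axial index `j` is 1-based counting
#' upward from the root tip (the start of the EZ); the top of the root is
#' aligned with the soil surface.
#'
#' @param config geometry settings from [geometry_config()].
#' @return An object of class `root_geometry` with fields
#'   \describe{
#'   \item{layer_thicknesses, xylem_radius}{as configured, um.}
#'   \item{layer_radii}{cumulative outer radii, xylem outward, um.}
#'   \item{r_in, r_out}{inner/outer radius per layer (outermost first), um.}
#'   \item{layer_centers}{radial mid-point per layer, um.}
#'   \item{cell_heights}{axial heights h_j, um.}
#'   \item{n_axial, n_layers}{grid dimensions.}
#'   \item{volumes}{matrix (layer x j) of compartment volumes, m^3.}
#'   \item{radial_areas}{matrix (boundary x j) of lateral areas 2*pi*r*h, m^2.}
#'   \item{axial_areas}{per-layer horizontal areas pi*(r_out^2 - r_in^2), m^2.}
#'   \item{z_centers}{depth of each compartment centre below the top of the
#'     root, m.}
#'   \item{root_length}{total length L, m.}
#'   }
#' @export
#' @examples
#' geom <- build_geometry(geometry_config(n_axial = 20))
#' geom$layer_radii      # 3 8 18 38 53 um with the default thicknesses
build_geometry <- function(config = geometry_config()) {
  thick <- config$layer_thicknesses
  # outer -> inner thickness list with the xylem core last
  r_out <- c(config$xylem_radius + sum(thick),  # epidermis outer = root surface
             config$xylem_radius + cumsum(rev(unname(thick)))[3:1],
             config$xylem_radius)
  r_in <- c(r_out[-1], 0)
  names(r_out) <- names(r_in) <- .layer_names

  n <- config$n_axial
  if (is.null(config$cell_heights)) {
    ez <- min(config$ez_end, n)
    if (ez == 1L) {
      h <- rep(config$h_max, n)
      h[1] <- config$h_max
    } else {
      ramp <- config$h_min + (config$h_max - config$h_min) *
        (seq_len(ez) - 1) / (ez - 1)
      h <- c(ramp, rep(config$h_max, max(0L, n - ez)))
    }
  } else {
    h <- as.numeric(config$cell_heights)
  }

  h_m <- h * 1e-6
  r_out_m <- r_out * 1e-6
  r_in_m <- r_in * 1e-6
  ann <- pi * (r_out_m^2 - r_in_m^2)              # per-layer annulus area, m^2
  volumes <- outer(ann, h_m)                       # layer x j
  dimnames(volumes) <- list(.layer_names, NULL)
  radial_areas <- outer(2 * pi * r_out_m, h_m)     # boundary b at r_out[b]
  dimnames(radial_areas) <- list(.boundary_names, NULL)

  top <- cumsum(h_m)                               # height of cell tops above tip
  L <- top[n]
  z_centers <- L - (top - h_m / 2)                 # depth below root top, m

  structure(list(
    layer_thicknesses = thick,
    xylem_radius = config$xylem_radius,
    layer_radii = unname(rev(r_out)),
    r_in = r_in, r_out = r_out,
    layer_centers = (r_in + r_out) / 2,
    cell_heights = h,
    n_axial = n, n_layers = 5L,
    ez_end = min(config$ez_end, n),
    volumes = volumes,
    radial_areas = radial_areas,
    axial_areas = stats::setNames(ann, .layer_names),
    z_centers = z_centers,
    root_length = L
  ), class = "root_geometry")
}

#' @export
print.root_geometry <- function(x, ...) {
  cat(sprintf("Model root geometry: %d layers x %d axial cells, L = %.3f mm\n",
              x$n_layers, x$n_axial, x$root_length * 1e3))
  cat(sprintf("  outer radius %.1f um; cell heights %.0f-%.0f um (EZ ramp to cell %d)\n",
              max(x$r_out), min(x$cell_heights), max(x$cell_heights), x$ez_end))
  invisible(x)
}

#' Tabulate the compartment grid
#'
#' One row per compartment with its layer, axial index, radii, height, volume
#' and centre depth — the plain-text geometry dump.
#'
#' @param geometry a [build_geometry()] object.
#' @return A tibble with columns `layer`, `j`, `r_in_um`, `r_out_um`, `h_um`,
#'   `volume_m3`, `z_center_m`.
#' @export
geometry_table <- function(geometry) {
  stopifnot(inherits(geometry, "root_geometry"))
  n <- geometry$n_axial
  tibble::tibble(
    layer = rep(.layer_names, times = n),
    j = rep(seq_len(n), each = 5L),
    r_in_um = rep(unname(geometry$r_in), times = n),
    r_out_um = rep(unname(geometry$r_out), times = n),
    h_um = rep(geometry$cell_heights, each = 5L),
    volume_m3 = as.vector(geometry$volumes),
    z_center_m = rep(geometry$z_centers, each = 5L)
  )
}

# linear development weight: 0 before `start`, 1 at start + ramp, linear
# between; w(start - 1) = 0 and w(start + ramp) = 1
ramp_weight <- function(j, start, ramp) {
  pmin(pmax((j - start + 1) / (ramp + 1), 0), 1)
}

#' Label developmental zones and development ramps
#'
#' Assigns each axial cell a developmental-zone label and computes the linear
#' development weights of the Casparian strip (CS) and of functional xylem.
#' The CS and functional xylem begin at the 12th cell from the start of the
#' EZ by default, ramping to full strength over `cs_ramp` (resp. `xylem_ramp`)
#' further cells; the suberin lamellae (SL) may appear from the 38th cell.
#'
#' Zone labels: `EZ` for cells up to the end of the height ramp, `transition`
#' while the CS or xylem weight is strictly between its start and 1, `DZ`
#' afterwards.
#'
#' @param geometry a [build_geometry()] object.
#' @param cs_start axial cell where the CS begins developing.
#' @param cs_ramp number of cells over which CS parameters ramp to full
#'   strength.
#' @param xylem_start axial cell where functional xylem begins developing.
#' @param xylem_ramp number of cells for the non-functional to functional
#'   xylem transition.
#' @param sl_start first axial cell at which SL may appear; a value above
#'   `n_axial` means no SL anywhere.
#' @return An object of class `zone_map`: list with `cs_start`, `cs_ramp`,
#'   `xylem_start`, `xylem_ramp`, `sl_start`, `ez_end`, `n_axial`, numeric
#'   weight vectors `w_cs` and `w_xylem` (per cell, in \[0,1\]) and the factor
#'   `zone` of labels.
#' @export
#' @examples
#' zm <- build_zone_map(build_geometry(geometry_config(n_axial = 40)))
#' zm$w_cs[11:16] # 0 at cell 11, 1 at cell 16
build_zone_map <- function(geometry, cs_start = 12, cs_ramp = 4,
                           xylem_start = 12, xylem_ramp = 4, sl_start = 38) {
  stopifnot(inherits(geometry, "root_geometry"))
  n <- geometry$n_axial
  if (cs_ramp < 0 || xylem_ramp < 0) {
    stop("development ramps must be non-negative", call. = FALSE)
  }
  if (cs_start < 1 || xylem_start < 1 || sl_start < 1) {
    stop("development start indices must be >= 1", call. = FALSE)
  }
  if (sl_start < cs_start) {
    stop("sl_start must not precede cs_start (SL forms after the CS)",
         call. = FALSE)
  }
  if (sl_start > n) {
    warning("sl_start exceeds n_axial: no suberin lamellae anywhere",
            call. = FALSE)
  }
  j <- seq_len(n)
  w_cs <- ramp_weight(j, cs_start, cs_ramp)
  w_xy <- ramp_weight(j, xylem_start, xylem_ramp)
  zone <- ifelse(j <= geometry$ez_end, "EZ",
                 ifelse(w_cs < 1 | w_xy < 1, "transition", "DZ"))
  structure(list(cs_start = as.integer(cs_start), cs_ramp = as.integer(cs_ramp),
                 xylem_start = as.integer(xylem_start),
                 xylem_ramp = as.integer(xylem_ramp),
                 sl_start = as.integer(sl_start),
                 ez_end = geometry$ez_end, n_axial = n,
                 w_cs = w_cs, w_xylem = w_xy,
                 zone = factor(zone, levels = c("EZ", "transition", "DZ"))),
            class = "zone_map")
}

#' @export
print.zone_map <- function(x, ...) {
  cat(sprintf("Zone map over %d axial cells: EZ to cell %d; CS from %d (+%d), xylem from %d (+%d), SL from %d\n",
              x$n_axial, x$ez_end, x$cs_start, x$cs_ramp,
              x$xylem_start, x$xylem_ramp, x$sl_start))
  invisible(x)
}
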