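#' Physical constants used by the transport model
#'
#' Returns the set of physical constants entering the flux laws: the gas
#' constant and Faraday constant (van't Hoff osmotic pressure and
#' electromigration), vacuum and relative permittivity (Poisson equation for
#' the electric potential), and the viscosity, density and gravitational
#' acceleration of water (Darcy xylem flow and hydrostatic heads).
#'
#' All values are SI. Temperature is not part of the tabulated parameter set
#' and defaults to 298.15 K.
#'
#' @param temperature absolute temperature, K.
#' @param relative_permittivity relative permittivity of the aqueous medium
#'   (dimensionless).
#' @param viscosity dynamic viscosity of water, Pa s.
#' @param water_density density of water, kg m^-3.
#' @param gravity gravitational acceleration, m s^-2.
#'
#' @return An object of class `physical_constants`: a named list with elements
#'   `R` (J mol^-1 K^-1), `T` (K), `F` (C mol^-1), `eps0` (F m^-1), `eps_r`,
#'   `mu` (Pa s), `rho` (kg m^-3), `g` (m s^-2).
#' @export
#' @examples
#' const <- physical_constants()
#' const$R * const$T # thermal energy scale, J mol^-1
physical_constants <- function(temperature = 298.15,
                               relative_permittivity = 80,
                               viscosity = 1.002e-3,
                               water_density = 1000,
                               gravity = 9.81) {
  vals <- list(temperature = temperature,
               relative_permittivity = relative_permittivity,
               viscosity = viscosity, water_density = water_density)
  for (nm in names(vals)) {
    if (!is.numeric(vals[[nm]]) || length(vals[[nm]]) != 1L || vals[[nm]] <= 0) {
      stop("physical constant '", nm, "' must be a positive scalar", call. = FALSE)
    }
  }
  if (gravity < 0) stop("gravity must be non-negative", call. = FALSE)
  structure(list(
    R = 8.314462618,
    T = temperature,
    F = 96485.33212,
    eps0 = 8.8541878128e-12,
    eps_r = relative_permittivity,
    mu = viscosity,
    rho = water_density,
    g = gravity
  ), class = "physical_constants")
}

#' @export
print.physical_constants <- function(x, ...) {
  cat("Physical constants (SI):\n")
  cat(sprintf("  R = %.6g J/mol/K, T = %.6g K, F = %.6g C/mol\n", x$R, x$T, x$F))
  cat(sprintf("  eps0 = %.6g F/m, eps_r = %.6g\n", x$eps0, x$eps_r))
  cat(sprintf("  mu = %.6g Pa s, rho = %.6g kg/m^3, g = %.6g m/s^2\n",
              x$mu, x$rho, x$g))
  invisible(x)
}
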