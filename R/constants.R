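#' Physical constants and unit helpers
#'
#' Internal unit conventions: lengths in micrometres, forces in piconewtons,
#' stiffnesses in pN/um, times in seconds, energies in pN um. SI is used only
#' for the rod-mechanics closed forms (N m^2, m^4, Pa), i.e. at the reporting
#' boundary.
#'
#' @name constants
#' @keywords internal
NULL

#' Boltzmann constant in J/K (exact, SI definition).
#' @export
KB_SI <- 1.380649e-23

#' Default absolute temperature in kelvin.
#'
#' 295 K is the working room temperature; with l_p = 0.39 um it reproduces a
#' filament flexural rigidity of 1.59e-27 N m^2 to three significant figures.
#' @export
DEFAULT_TEMPERATURE_K <- 295

#' Thermal energy k_B T in pN um at a given temperature.
#'
#' @param temperature_k temperature in kelvin
#' @return thermal energy in pN um (1 J = 1e18 pN um)
#' @export
kbt_pn_um <- function(temperature_k = DEFAULT_TEMPERATURE_K) {
  KB_SI * temperature_k * 1e18
}

#' Stokes drag coefficient of a sphere, in pN s/um.
#'
#' gamma = 6 pi eta r. With eta in Pa s and r in um the SI value (N s/m) is
#' converted to pN s/um (factor 1e6).
#'
#' @param bead_radius_um bead radius in um
#' @param viscosity_pa_s dynamic viscosity in Pa s (water: 1e-3)
#' @return drag coefficient in pN s/um
#' @export
stokes_drag <- function(bead_radius_um, viscosity_pa_s = 1e-3) {
  stopifnot(bead_radius_um > 0, viscosity_pa_s > 0)
  6 * pi * viscosity_pa_s * (bead_radius_um * 1e-6) * 1e6
}

`%||%` <- function(a, b) if (is.null(a)) b else a
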