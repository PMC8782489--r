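#' Physical constants used throughout the package
#'
#' Single source of truth for the gas constant, Avogadro's number and derived
#' thermal energies.  Melting thermodynamics are expressed in kcal/mol (the
#' unit of the UV-melting literature); mechanical and free-energy modules use
#' kJ/mol.
#'
#' @return A named list with elements `R_kcal` (kcal/mol/K), `R_kJ`
#'   (kJ/mol/K) and `N_A` (1/mol).
#' @examples
#' phys_constants()$R_kcal
#' @export
phys_constants <- function() {
  list(
    R_kcal = 1.987204e-3,
    R_kJ   = 8.314462618e-3,
    N_A    = 6.02214076e23
  )
}

#' Thermal energy k_B T in kJ/mol
#'
#' @param temperature Temperature in kelvin.
#' @return Molar thermal energy in kJ/mol (2.494 kJ/mol at 300 K).
#' @export
kBT_kJ <- function(temperature = 300) {
  phys_constants()$R_kJ * temperature
}

#' Unit conversions
#'
#' @param x Numeric vector.
#' @return Converted numeric vector.
#' @name unit-conversions
NULL

#' @rdname unit-conversions
#' @export
kcal_to_kJ <- function(x) x * 4.184

#' @rdname unit-conversions
#' @export
kJ_to_kcal <- function(x) x / 4.184

#' @rdname unit-conversions
#' @export
celsius_to_kelvin <- function(x) x + 273.15

#' @rdname unit-conversions
#' @export
kelvin_to_celsius <- function(x) x - 273.15
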