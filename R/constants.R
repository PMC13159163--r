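# Physical constants (SI). All internal computation is strictly SI:
# kelvin, kilogram, metre, joule. Celsius appears only at I/O boundaries.

#' Physical constants used throughout
#'
#' Boltzmann constant (J/K), Avogadro constant (1/mol) and the molar gas
#' constant (J/mol/K), CODATA exact values.
#' @keywords internal
KB <- 1.380649e-23

#' @rdname KB
#' @keywords internal
N_AVOGADRO <- 6.02214076e23

#' @rdname KB
#' @keywords internal
R_GAS <- KB * N_AVOGADRO

# Rate at which nucleation is considered "relevant" on experimental
# timescales (one nucleus per 100 s in a nanolitre), used as the default
# threshold for driving-force and supercooling crossings.
J_RELEVANT <- 1e12 # m^-3 s^-1

#' Convert between Celsius and Kelvin
#'
#' Helpers for the I/O boundary; everything inside the package is in kelvin.
#'
#' @param TC temperature in degrees Celsius
#' @param TK temperature in kelvin
#' @return temperature in the other unit
#' @export
celsius_to_kelvin <- function(TC) TC + 273.15

#' @rdname celsius_to_kelvin
#' @export
kelvin_to_celsius <- function(TK) TK - 273.15
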