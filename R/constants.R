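#' Physical constants used throughout the package
#'
#' Returns the fixed unit conventions of the package: energies in kcal/mol,
#' distances in Angstrom, masses in amu, charges in elementary charges,
#' temperatures in Kelvin.
#'
#' @return A named list with elements `coulomb` (Coulomb prefactor,
#'   332.0636 kcal*A/(mol*e^2)), `kB` (Boltzmann constant,
#'   0.0019872041 kcal/(mol*K)) and `time_unit_fs` (internal MD time unit,
#'   48.88821 fs, the AKMA convention).
#' @export
#' @examples
#' evb_constants()$kB
evb_constants <- function() {
  list(coulomb = 332.0636, kB = 0.0019872041, time_unit_fs = 48.88821)
}

.KB <- 0.0019872041
.COULOMB <- 332.0636
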