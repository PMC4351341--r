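## Unit system: Angstrom, femtosecond, amu, kcal/mol, Kelvin.

#' Physical constants of the simulation unit system
#'
#' The package works in Angstrom / femtosecond / amu / kcal mol^-1 units.
#' `kBoltzmann()` returns Boltzmann's constant in kcal mol^-1 K^-1.
#' `accelUnit()` returns the conversion factor from (kcal mol^-1 A^-1) / amu
#' to A fs^-2, i.e. the factor by which F/m must be multiplied to obtain an
#' acceleration in internal units. Its inverse converts amu A^2 fs^-2 to
#' kcal mol^-1 (kinetic-energy conversion).
#'
#' @return A scalar numeric.
#' @export
kBoltzmann <- function() 1.987204259e-3

#' @rdname kBoltzmann
#' @export
accelUnit <- function() 4.184e-4

## internal shorthands
.kB <- 1.987204259e-3
.acc <- 4.184e-4
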