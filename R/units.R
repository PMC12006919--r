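#' Unit conventions used throughout the package
#'
#' All quantities use the conventional biomolecular-simulation units:
#' lengths in angstrom, energies in kcal/mol, forces in kcal/mol/A,
#' charges in elementary charge units, masses in amu and times in fs.
#' The Coulomb constant and the acceleration conversion factor (from
#' (kcal/mol/A)/amu to A/fs^2) are fixed at build time and are the single
#' source of truth for every force term.
#'
#' @return Named list with elements `length`, `energy`, `force`, `charge`,
#'   `mass`, `time`, `coulomb_constant` (332.0637 kcal*A/(mol*e^2)) and
#'   `accel_conversion` (4.184e-4 A/fs^2 per (kcal/mol/A)/amu).
#' @export
#' @examples
#' unit_constants()$coulomb_constant
unit_constants <- function() {
  list(
    length = "angstrom",
    energy = "kcal/mol",
    force = "kcal/mol/angstrom",
    charge = "e",
    mass = "amu",
    time = "fs",
    coulomb_constant = 332.0637,
    accel_conversion = 4.184e-4
  )
}

# internal shorthands
.KCOULOMB <- 332.0637
.ACCEL <- 4.184e-4
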