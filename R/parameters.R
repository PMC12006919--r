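#' Packaged default bead parameter table
#'
#' Covers the 20 amino acids plus generic nucleotide beads. Radii and well
#' depths are residue-level effective values (synthetic stand-ins, not
#' taken from any published force field); transfer energies are signed by a
#' standard hydrophobicity ordering, negative = hydrophobic (prefers the
#' membrane core). The table is plain data shipped with the package; tests
#' that depend on numbers pin this version.
#'
#' @return data.frame with columns `name`, `charge` (e), `radius` (A),
#'   `epsilon` (kcal/mol), `mass` (amu), `transfer_energy` (kcal/mol).
#' @export
default_parameter_table <- function() {
  path <- system.file("extdata", "bead_parameters.csv", package = "aenm",
                      mustWork = TRUE)
  read_parameter_table(path)
}

#' Read a bead parameter table from a delimited text file
#'
#' @param path CSV file with header
#'   `name,charge,radius,epsilon,mass,transfer_energy`.
#' @return data.frame as in [default_parameter_table()].
#' @export
read_parameter_table <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("name", "charge", "radius", "epsilon", "mass", "transfer_energy")
  miss <- setdiff(need, names(tab))
  if (length(miss))
    stop("parameter table missing columns: ", paste(miss, collapse = ", "))
  tab
}

#' Assign physical parameters to every particle
#'
#' Each particle is matched against the table first by particle name, then
#' by residue name (a particle-name rule therefore overrides a residue-name
#' rule). Unmatched particles receive the declared fallback defaults and
#' are reported in the `unmatched` attribute; nothing is fatal.
#'
#' @param system a `particle_system`.
#' @param table parameter data.frame (see [default_parameter_table()]).
#' @param defaults named list of fallback values for unmatched particles.
#' @param keep_charge if `TRUE`, charges already present on the particles
#'   (e.g. from a PQR file or from coarse-grain summation) are kept and
#'   only zero charges are overwritten from the table.
#' @return the `particle_system` with parameters set; attribute `unmatched`
#'   holds the names that fell through to the defaults.
#' @export
assign_parameters <- function(system, table = default_parameter_table(),
                              defaults = list(charge = 0, radius = 3.0,
                                              epsilon = 0.2, mass = 100,
                                              transfer_energy = 0),
                              keep_charge = FALSE) {
  at <- system$atoms
  hit_particle <- match(at$name, table$name)
  hit_residue <- match(at$resname, table$name)
  row <- ifelse(!is.na(hit_particle), hit_particle, hit_residue)
  unmatched <- unique(at$resname[is.na(row)])
  pick <- function(col) {
    v <- ifelse(is.na(row), defaults[[col]], table[[col]][row])
    as.numeric(v)
  }
  newq <- pick("charge")
  at$charge <- if (keep_charge) ifelse(at$charge != 0, at$charge, newq) else newq
  at$radius <- pick("radius")
  at$epsilon <- pick("epsilon")
  at$mass <- pick("mass")
  at$transfer_energy <- pick("transfer_energy")
  system$atoms <- at
  attr(system, "unmatched") <- unmatched
  system
}
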