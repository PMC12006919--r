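#' Create a particle system
#'
#' A particle system is an ordered set of coarse-grained beads (or atoms),
#' each carrying a position and the physical parameters used by the force
#' terms: charge (e), radius (A), Lennard-Jones well depth epsilon
#' (kcal/mol), mass (amu) and a membrane transfer energy (kcal/mol,
#' negative = hydrophobic). The `dynamic` flag separates the mobile set
#' from the static set of immobile particles: static particles exert
#' forces but are never moved by the integrator.
#'
#' @param atoms data.frame with columns `name`, `resname`, `resid`,
#'   `chain`, `x`, `y`, `z` and optionally `charge`, `radius`, `epsilon`,
#'   `mass`, `transfer_energy`, `dynamic` (missing columns are filled with
#'   zero-parameter defaults and `dynamic = TRUE`).
#' @param name label for the system.
#' @return Object of class `particle_system`: a list with elements
#'   `atoms` (completed data.frame) and `name`.
#' @export
#' @examples
#' ps <- particle_system(data.frame(
#'   name = "CA", resname = "GLY", resid = 1:3, chain = "A",
#'   x = c(0, 5, 10), y = 0, z = 0))
#' n_particles(ps)
particle_system <- function(atoms, name = "system") {
  stopifnot(is.data.frame(atoms))
  if (nrow(atoms) < 1L)
    stop("a particle system needs at least one particle")
  need <- c("name", "resname", "resid", "chain", "x", "y", "z")
  miss <- setdiff(need, names(atoms))
  if (length(miss))
    stop("missing required columns: ", paste(miss, collapse = ", "))
  defaults <- list(charge = 0, radius = 0, epsilon = 0, mass = 0,
                   transfer_energy = 0, dynamic = TRUE)
  for (cn in names(defaults))
    if (is.null(atoms[[cn]])) atoms[[cn]] <- defaults[[cn]]
  pos <- as.matrix(atoms[, c("x", "y", "z")])
  if (!all(is.finite(pos)))
    stop("particle positions must be finite")
  if (any(atoms$radius < 0)) stop("particle radius must be >= 0")
  if (any(atoms$mass < 0)) stop("particle mass must be >= 0")
  rownames(atoms) <- NULL
  structure(list(atoms = atoms, name = name), class = "particle_system")
}

#' Number of particles in a system
#' @param system a `particle_system`.
#' @return integer count.
#' @export
n_particles <- function(system) nrow(system$atoms)

#' Extract the coordinate matrix of a system
#' @param system a `particle_system`.
#' @return N x 3 numeric matrix (columns x, y, z, in A).
#' @export
get_coords <- function(system) {
  m <- as.matrix(system$atoms[, c("x", "y", "z")])
  dimnames(m) <- list(NULL, c("x", "y", "z"))
  m
}

#' Replace the coordinates of a system
#' @param system a `particle_system`.
#' @param coords N x 3 matrix.
#' @return the updated `particle_system`.
#' @export
set_coords <- function(system, coords) {
  coords <- as_coord_matrix(coords, n_particles(system))
  system$atoms$x <- coords[, 1]
  system$atoms$y <- coords[, 2]
  system$atoms$z <- coords[, 3]
  system
}

#' @export
print.particle_system <- function(x, ...) {
  cat(sprintf("particle_system '%s': %d particles, %d chains, %d dynamic\n",
              x$name, nrow(x$atoms), length(unique(x$atoms$chain)),
              sum(x$atoms$dynamic)))
  invisible(x)
}

# coerce/validate an N x 3 coordinate matrix
as_coord_matrix <- function(coords, n = NULL) {
  coords <- as.matrix(coords)
  if (is.null(dim(coords)) || ncol(coords) != 3L)
    stop("coordinates must be an N x 3 matrix")
  if (!is.null(n) && nrow(coords) != n)
    stop(sprintf("coordinate shape mismatch: %d rows for %d particles",
                 nrow(coords), n))
  storage.mode(coords) <- "double"
  coords
}
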