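#' Create a force term
#'
#' Uniform contract shared by all energy contributions: given an N x 3
#' coordinate matrix, `evaluate` returns `list(energy, forces)` with
#' forces of the system's shape. Disabled terms contribute exactly zero.
#'
#' @param name term label used in energy reports and error messages.
#' @param evaluate function(coords) -> list(energy, forces).
#' @param enabled logical.
#' @return object of class `force_term`.
#' @export
force_term <- function(name, evaluate, enabled = TRUE) {
  stopifnot(is.character(name), is.function(evaluate))
  structure(list(name = name, evaluate = evaluate, enabled = enabled),
            class = "force_term")
}

#' Spring-network force term
#' @param net a `spring_network`.
#' @param enabled logical.
#' @return a `force_term` named `"springs"`.
#' @export
spring_term <- function(net, enabled = TRUE) {
  force_term("springs", function(coords) spring_energy_forces(net, coords),
             enabled = enabled)
}

#' Non-bonded (Lennard-Jones + Coulomb) force terms
#'
#' Builds the two non-bonded terms sharing one cell-grid neighbour search.
#' Pairs connected by a spring are excluded from both terms (the bonded-
#' exclusion analogue: spring neighbours often sit closer than the LJ
#' contact distance). The neighbour list is rebuilt at each evaluation
#' from a cell grid with `cell_size = max(lj_cutoff, coulomb_cutoff)`.
#'
#' @param system a `particle_system` (supplies radii, epsilons, charges).
#' @param net optional `spring_network` whose pairs are excluded.
#' @param lj_cutoff Lennard-Jones truncation (A), default 12.
#' @param coulomb_cutoff Coulomb truncation (A), default 16.
#' @param dielectric relative dielectric, default 1.
#' @param lj_enabled,coulomb_enabled logical.
#' @return list of two `force_term`s named `"lj"` and `"coulomb"`.
#' @export
nonbonded_terms <- function(system, net = NULL, lj_cutoff = 12,
                            coulomb_cutoff = 16, dielectric = 1,
                            lj_enabled = TRUE, coulomb_enabled = TRUE) {
  at <- system$atoms
  excl <- if (!is.null(net)) spring_pairs(net) else NULL
  cell <- max(lj_cutoff, coulomb_cutoff)
  n <- n_particles(system)
  get_pairs <- function(coords) {
    if (n > 200L) {
      grid <- build_cell_grid(coords, cell_size = cell)
      neighbor_pairs(grid, coords, cell, exclusions = excl)
    } else brute_force_pairs(coords, cell, exclusions = excl)
  }
  list(
    force_term("lj", function(coords)
      lj_energy_forces(get_pairs(coords), coords, at$radius, at$epsilon,
                       cutoff = lj_cutoff), enabled = lj_enabled),
    force_term("coulomb", function(coords)
      coulomb_energy_forces(get_pairs(coords), coords, at$charge,
                            dielectric = dielectric,
                            cutoff = coulomb_cutoff),
      enabled = coulomb_enabled))
}

#' Grid-field force term
#' @param grid a `scalar_grid`.
#' @param system a `particle_system`; couplings are charges in potential
#'   mode and `weight * |transfer-independent| fitting weights` in density
#'   mode (see `weight`).
#' @param weight global multiplier; in density mode the per-particle
#'   coupling is `weight` for every particle, in potential mode the charge
#'   is multiplied by `weight`.
#' @param enabled logical.
#' @return a `force_term` named `"field"`.
#' @export
field_term <- function(grid, system, weight = 1, enabled = TRUE) {
  couplings <- if (grid$mode == "potential")
    system$atoms$charge * weight else rep(weight, n_particles(system))
  force_term("field", function(coords)
    field_energy_forces(grid, coords, couplings), enabled = enabled)
}

#' Implicit-membrane force term
#' @param mem a `membrane_model`.
#' @param system a `particle_system` (supplies transfer energies).
#' @param enabled logical.
#' @return a `force_term` named `"membrane"`.
#' @export
membrane_term <- function(mem, system, enabled = TRUE) {
  t_e <- system$atoms$transfer_energy
  force_term("membrane", function(coords)
    membrane_energy_forces(mem, t_e, coords), enabled = enabled)
}

#' Surface-burial force term
#'
#' Weights default to `-0.01 * transfer_energy` (kcal/mol/A^2): a
#' hydrophobic bead (negative transfer energy) gets a positive weight, so
#' losing accessible area on association (dA < 0) lowers the energy.
#'
#' @param system a `particle_system`.
#' @param areas_reference reference areas (A^2); computed from the
#'   system's own coordinates if omitted.
#' @param weights per-particle weights; default `-0.01 * transfer_energy`.
#' @param probe_radius,n_points see [shrake_rupley()].
#' @param mode `"score"` (default, zero forces) or `"finite_difference"`.
#' @param enabled logical.
#' @return a `force_term` named `"sasa"` with the latest per-bead areas
#'   stashed in an environment for observables.
#' @export
sasa_term <- function(system, areas_reference = NULL, weights = NULL,
                      probe_radius = 1.4, n_points = 256,
                      mode = c("score", "finite_difference"),
                      enabled = TRUE) {
  mode <- match.arg(mode)
  at <- system$atoms
  if (is.null(weights)) weights <- -0.01 * at$transfer_energy
  if (is.null(areas_reference))
    areas_reference <- shrake_rupley(get_coords(system), at$radius,
                                     probe_radius, n_points)
  cache <- new.env(parent = emptyenv())
  cache$areas <- areas_reference
  tm <- force_term("sasa", function(coords) {
    r <- sasa_energy_forces(coords, at$radius, weights, areas_reference,
                            probe_radius, n_points, mode = mode)
    cache$areas <- r$areas
    list(energy = r$energy, forces = r$forces)
  }, enabled = enabled)
  tm$cache <- cache
  tm
}

#' Total energy and forces over a list of force terms
#'
#' Element-wise sum of forces and an itemized energy report whose `total`
#' equals the sum of the parts. A term returning non-finite values aborts
#' with an error naming the term.
#'
#' @param terms non-empty list of `force_term`s (at least one enabled).
#' @param coords N x 3 coordinate matrix.
#' @return list with `report` (named per-term energies plus `total`) and
#'   `forces` (N x 3).
#' @export
total_energy_forces <- function(terms, coords) {
  stopifnot(is.list(terms), length(terms) >= 1L)
  coords <- as_coord_matrix(coords)
  n <- nrow(coords)
  forces <- matrix(0, n, 3)
  energies <- numeric(0)
  any_enabled <- FALSE
  for (tm in terms) {
    stopifnot(inherits(tm, "force_term"))
    if (!tm$enabled) next
    any_enabled <- TRUE
    r <- tm$evaluate(coords)
    if (!is.finite(r$energy) || !all(is.finite(r$forces)))
      stop(sprintf("force term '%s' returned non-finite values", tm$name))
    if (!all(dim(r$forces) == c(n, 3)))
      stop(sprintf("force term '%s' returned forces of the wrong shape", tm$name))
    nm <- tm$name
    while (nm %in% names(energies)) nm <- paste0(nm, "'")
    energies[nm] <- r$energy
    forces <- forces + r$forces
  }
  if (!any_enabled) stop("no enabled force term")
  report <- c(as.list(energies), list(total = sum(energies)))
  list(report = report, forces = forces)
}
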