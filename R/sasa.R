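#' Deterministic golden-spiral point set on the unit sphere
#'
#' Fibonacci/golden-spiral lattice: near-uniform, fully deterministic (no
#' randomness), so surface areas are bit-reproducible across runs and
#' platforms.
#'
#' @param n number of points (>= 1).
#' @return n x 3 matrix of unit vectors.
#' @export
golden_spiral_points <- function(n) {
  stopifnot(n >= 1)
  k <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * k / n)
  theta <- pi * (1 + sqrt(5)) * k
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' Shrake-Rupley solvent-accessible surface area per bead
#'
#' Each bead's expanded sphere (radius + probe) is sampled with a fixed
#' golden-spiral lattice; a sample point is accessible iff it lies
#' strictly outside every other bead's expanded sphere (boundary-touching
#' points count as buried). The per-bead area is
#' `4*pi*(r_i + probe)^2 * accessible/n_points`.
#'
#' @param coords N x 3 coordinate matrix (A).
#' @param radii per-particle radii (A), all >= 0.
#' @param probe_radius solvent probe radius (A), default 1.4 (water).
#' @param n_points lattice points per sphere, >= 32; default 256.
#' @return numeric vector of per-particle areas (A^2).
#' @export
#' @examples
#' # isolated sphere: exactly the closed-form expanded-sphere area
#' shrake_rupley(matrix(0, 1, 3), radii = 1.6)  # 4*pi*3^2
shrake_rupley <- function(coords, radii, probe_radius = 1.4, n_points = 256) {
  coords <- as_coord_matrix(coords)
  n <- nrow(coords)
  radii <- rep_len(as.numeric(radii), n)
  if (any(radii < 0)) stop("negative radius")
  if (n_points < 32) stop("n_points must be >= 32")
  pts <- golden_spiral_points(n_points)
  rexp <- radii + probe_radius
  areas <- numeric(n)
  for (i in seq_len(n)) {
    # candidate occluders: expanded spheres that can reach bead i's surface
    dvec <- sweep(coords, 2, coords[i, ])
    d <- sqrt(rowSums(dvec * dvec))
    nb <- which(d < rexp[i] + rexp & seq_len(n) != i)
    if (length(nb) == 0L) { areas[i] <- 4 * pi * rexp[i]^2; next }
    surf <- sweep(pts * rexp[i], 2, coords[i, ], "+")
    acc <- rep(TRUE, n_points)
    for (j in nb) {
      dj <- sweep(surf, 2, coords[j, ])
      acc <- acc & (rowSums(dj * dj) > rexp[j]^2)  # strictly outside
      if (!any(acc)) break
    }
    areas[i] <- 4 * pi * rexp[i]^2 * sum(acc) / n_points
  }
  areas
}

#' Surface-burial (pseudo-hydrophobic aggregation) energy
#'
#' Reference-anchored linear penalty,
#' `E = sum_i w_i (A_i,now - A_i,ref)`, where the reference areas are
#' precomputed on the isolated molecules so the term is exactly zero
#' before contact. Under the packaged sign convention hydrophobic beads
#' carry a positive weight (`-0.01 * transfer_energy`, and transfer
#' energies are negative for hydrophobic beads), so burying them on
#' association (dA < 0) lowers the energy: the term is an association
#' driver, not a folding potential. A hydrophobic bead with weight 0.01
#' that loses 50 A^2 on contact contributes -0.5 kcal/mol.
#'
#' @param areas_now current per-particle areas (A^2).
#' @param areas_reference reference areas on the isolated parts (A^2).
#' @param weights per-particle weights (kcal/mol/A^2).
#' @return scalar energy (kcal/mol).
#' @export
burial_energy <- function(areas_now, areas_reference, weights) {
  if (length(areas_now) != length(areas_reference) ||
      length(areas_now) != length(weights))
    stop("shape mismatch between areas and weights")
  sum(weights * (areas_now - areas_reference))
}

#' Surface-burial energy and (optional finite-difference) forces
#'
#' The burial term is experimental and defaults to score-only: it reports
#' the energy as an observable and contributes an exactly-zero force. With
#' `mode = "finite_difference"` central differences (step `fd_step`) of
#' [burial_energy()] provide forces, computed only for beads whose
#' neighbourhood can change the area (beads with at least one contact
#' partner within reach -- the "dirty" set); isolated beads have constant
#' area and exactly zero force.
#'
#' @param coords N x 3 coordinate matrix (A).
#' @param radii per-particle radii (A).
#' @param weights per-particle weights (kcal/mol/A^2).
#' @param areas_reference reference per-particle areas (A^2).
#' @param probe_radius,n_points as in [shrake_rupley()].
#' @param mode `"score"` (default) or `"finite_difference"`.
#' @param fd_step central-difference step (A), default 0.05.
#' @return list with `energy`, `forces` (N x 3) and `areas`.
#' @export
sasa_energy_forces <- function(coords, radii, weights, areas_reference,
                               probe_radius = 1.4, n_points = 256,
                               mode = c("score", "finite_difference"),
                               fd_step = 0.05) {
  mode <- match.arg(mode)
  coords <- as_coord_matrix(coords)
  n <- nrow(coords)
  radii <- rep_len(as.numeric(radii), n)
  weights <- rep_len(as.numeric(weights), n)
  areas <- shrake_rupley(coords, radii, probe_radius, n_points)
  energy <- burial_energy(areas, areas_reference, weights)
  forces <- matrix(0, n, 3)
  if (mode == "finite_difference" && n > 1L) {
    rexp <- radii + probe_radius
    d <- as.matrix(stats::dist(coords))
    reach <- outer(rexp, rexp, "+") + rexp + 2 * fd_step
    diag(d) <- Inf
    dirty <- which(apply(d < reach, 1, any))
    for (i in dirty) {
      for (a in 1:3) {
        cp <- coords; cp[i, a] <- cp[i, a] + fd_step
        ep <- burial_energy(shrake_rupley(cp, radii, probe_radius, n_points),
                            areas_reference, weights)
        cm <- coords; cm[i, a] <- cm[i, a] - fd_step
        em <- burial_energy(shrake_rupley(cm, radii, probe_radius, n_points),
                            areas_reference, weights)
        forces[i, a] <- -(ep - em) / (2 * fd_step)
      }
    }
  }
  list(energy = energy, forces = forces, areas = areas)
}
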