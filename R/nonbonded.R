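#' Lennard-Jones energy and forces over a pair list
#'
#' 12-6 potential in the (R_min, epsilon) convention:
#' `E(d) = eps[(R/d)^12 - 2(R/d)^6]` with `R = r_i + r_j` (contact distance
#' = sum of radii) and `eps = sqrt(eps_i eps_j)`. The minimum is at d = R
#' with depth -eps. The potential is truncated and energy-shifted to zero
#' at the cutoff (per pair, since the shift depends on R); pairs beyond the
#' cutoff contribute nothing.
#'
#' @param pairs 2-column integer matrix (i, j), e.g. from
#'   [neighbor_pairs()]; spring-bonded pairs should be excluded upstream.
#' @param coords N x 3 coordinate matrix (A).
#' @param radii per-particle radii (A).
#' @param epsilons per-particle well depths (kcal/mol).
#' @param cutoff truncation distance (A); `Inf` disables the shift.
#' @return list with `energy` and `forces` (N x 3).
#' @export
lj_energy_forces <- function(pairs, coords, radii, epsilons, cutoff = 12) {
  coords <- as_coord_matrix(coords)
  n <- nrow(coords)
  if (is.null(pairs) || nrow(pairs) == 0L)
    return(list(energy = 0, forces = matrix(0, n, 3)))
  i <- pairs[, 1]; j <- pairs[, 2]
  dr <- coords[i, , drop = FALSE] - coords[j, , drop = FALSE]
  d <- sqrt(rowSums(dr * dr))
  if (any(d == 0)) stop("zero interparticle distance in Lennard-Jones term")
  R <- radii[i] + radii[j]
  eps <- sqrt(epsilons[i] * epsilons[j])
  live <- d <= cutoff & eps > 0
  energy <- 0
  forces <- matrix(0, n, 3)
  if (any(live)) {
    dl <- d[live]; Rl <- R[live]; el <- eps[live]
    s6 <- (Rl / dl)^6
    e_pair <- el * (s6 * s6 - 2 * s6)
    if (is.finite(cutoff)) {
      sc6 <- (Rl / cutoff)^6
      e_pair <- e_pair - el * (sc6 * sc6 - 2 * sc6)
    }
    energy <- sum(e_pair)
    # dE/dd = -12 eps/d (s12 - s6); force on i = -dE/dd * dr/d
    dEdd <- -12 * el / dl * (s6 * s6 - s6)
    fi <- dr[live, , drop = FALSE] * (-dEdd / dl)
    forces <- accumulate_forces(n, i[live], j[live], fi)
  }
  list(energy = energy, forces = forces)
}

#' Coulomb energy and forces over a pair list
#'
#' `E = k_e q_i q_j / (eps_r d)` with k_e = 332.0637 kcal*A/(mol*e^2),
#' truncated and shifted to zero at the cutoff.
#'
#' @param pairs 2-column integer matrix (i, j).
#' @param coords N x 3 coordinate matrix (A).
#' @param charges per-particle charges (e).
#' @param dielectric relative dielectric constant (> 0); use 1 when an
#'   external Poisson-Boltzmann grid already embodies solvent screening.
#' @param cutoff truncation distance (A); `Inf` disables the shift.
#' @return list with `energy` and `forces` (N x 3).
#' @export
coulomb_energy_forces <- function(pairs, coords, charges, dielectric = 1,
                                  cutoff = 16) {
  if (!is.numeric(dielectric) || dielectric <= 0)
    stop("dielectric must be > 0")
  coords <- as_coord_matrix(coords)
  n <- nrow(coords)
  if (is.null(pairs) || nrow(pairs) == 0L)
    return(list(energy = 0, forces = matrix(0, n, 3)))
  i <- pairs[, 1]; j <- pairs[, 2]
  dr <- coords[i, , drop = FALSE] - coords[j, , drop = FALSE]
  d <- sqrt(rowSums(dr * dr))
  if (any(d == 0)) stop("zero interparticle distance in Coulomb term")
  qq <- .KCOULOMB * charges[i] * charges[j] / dielectric
  live <- d <= cutoff & qq != 0
  energy <- 0
  forces <- matrix(0, n, 3)
  if (any(live)) {
    dl <- d[live]; ql <- qq[live]
    e_pair <- ql / dl
    if (is.finite(cutoff)) e_pair <- e_pair - ql / cutoff
    energy <- sum(e_pair)
    # dE/dd = -qq/d^2; force on i = -dE/dd * dr/d = qq/d^3 * dr
    fi <- dr[live, , drop = FALSE] * (ql / dl^3)
    forces <- accumulate_forces(n, i[live], j[live], fi)
  }
  list(energy = energy, forces = forces)
}
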