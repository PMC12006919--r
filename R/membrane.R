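#' Define an implicit planar membrane model
#'
#' Analytic implicit bilayer: each bead gains (or pays) its transfer
#' energy, weighted by a smooth insertion profile of its depth. The
#' profile is a symmetric logistic in `|z - center_z|`,
#' `f(z) = 1/(1 + exp((|z - center_z| - h)/w))`, equal to 1 deep inside
#' the slab, 0.5 exactly at the interface and 0 in water. An optional
#' second bilayer (e.g. the two membranes of a gram-negative envelope) is
#' combined by a per-bead maximum of the two profiles. The membrane normal
#' is fixed to +z; inputs are assumed pre-oriented.
#'
#' @param center_z midplane of bilayer 1 (A).
#' @param half_thickness h (A): half the hydrophobic slab thickness,
#'   default 15 (a ~30 A slab).
#' @param interface_width w (A): interface softness, default 1.5.
#' @param scale unitless global multiplier on transfer energies.
#' @param second_center_z optional midplane of a second, non-overlapping
#'   bilayer (must be more than 2h away from `center_z`).
#' @return object of class `membrane_model`.
#' @export
membrane_model <- function(center_z = 0, half_thickness = 15,
                           interface_width = 1.5, scale = 1,
                           second_center_z = NULL) {
  if (half_thickness <= 0) stop("half_thickness must be > 0")
  if (interface_width <= 0) stop("interface_width must be > 0")
  if (!is.null(second_center_z) &&
      abs(second_center_z - center_z) <= 2 * half_thickness)
    stop("second bilayer overlaps the first (centers closer than 2*half_thickness)")
  structure(list(center_z = center_z, half_thickness = half_thickness,
                 interface_width = interface_width, scale = scale,
                 second_center_z = second_center_z),
            class = "membrane_model")
}

profile_one <- function(z, center, h, w) 1 / (1 + exp((abs(z - center) - h) / w))

# d f/d z for one bilayer
profile_one_deriv <- function(z, center, h, w) {
  f <- profile_one(z, center, h, w)
  -sign(z - center) / w * f * (1 - f)
}

#' Membrane insertion profile
#'
#' @param mem a `membrane_model`.
#' @param z numeric vector of z coordinates (A).
#' @return f in [0, 1]; for a double membrane, the per-point maximum over
#'   the two bilayers.
#' @export
insertion_profile <- function(mem, z) {
  f <- profile_one(z, mem$center_z, mem$half_thickness, mem$interface_width)
  if (!is.null(mem$second_center_z)) {
    f2 <- profile_one(z, mem$second_center_z, mem$half_thickness,
                      mem$interface_width)
    f <- pmax(f, f2)
  }
  f
}

#' Implicit-membrane energy and forces
#'
#' `E = scale * sum_i t_i f(z_i)` where `t_i` is the particle's transfer
#' energy (negative = hydrophobic, rewarded inside the slab). Forces act
#' along z only: `F_z,i = -scale * t_i * f'(z_i)`. For a double membrane
#' each bead uses the bilayer whose profile dominates at its position.
#'
#' @param mem a `membrane_model`.
#' @param transfer_energies per-particle transfer energies (kcal/mol).
#' @param coords N x 3 coordinate matrix (A).
#' @return list with `energy` and `forces` (N x 3).
#' @export
membrane_energy_forces <- function(mem, transfer_energies, coords) {
  coords <- as_coord_matrix(coords)
  z <- coords[, 3]
  t_e <- rep_len(as.numeric(transfer_energies), nrow(coords))
  f1 <- profile_one(z, mem$center_z, mem$half_thickness, mem$interface_width)
  if (is.null(mem$second_center_z)) {
    f <- f1
    df <- profile_one_deriv(z, mem$center_z, mem$half_thickness,
                            mem$interface_width)
  } else {
    f2 <- profile_one(z, mem$second_center_z, mem$half_thickness,
                      mem$interface_width)
    use2 <- f2 > f1
    f <- ifelse(use2, f2, f1)
    df <- ifelse(use2,
      profile_one_deriv(z, mem$second_center_z, mem$half_thickness,
                        mem$interface_width),
      profile_one_deriv(z, mem$center_z, mem$half_thickness,
                        mem$interface_width))
  }
  energy <- mem$scale * sum(t_e * f)
  forces <- matrix(0, nrow(coords), 3)
  forces[, 3] <- -mem$scale * t_e * df
  list(energy = energy, forces = forces)
}

#' Insertion depth of a selection
#'
#' Signed z-distance of the selection's geometric center from the bilayer
#' midplane; for a double membrane, relative to the nearer bilayer.
#'
#' @param mem a `membrane_model`.
#' @param coords N x 3 coordinate matrix (A).
#' @param sel non-empty `selection` (default: all particles).
#' @return signed depth (A).
#' @export
insertion_depth <- function(mem, coords, sel = NULL) {
  zc <- geometric_center(coords, sel)[3]
  d1 <- zc - mem$center_z
  if (is.null(mem$second_center_z)) return(d1)
  d2 <- zc - mem$second_center_z
  if (abs(d2) < abs(d1)) d2 else d1
}

#' Tilt angle of a molecular axis relative to the membrane normal
#'
#' The axis is the vector between the geometric centers of two selections
#' (e.g. the two ends of a helix or barrel); the tilt is the angle between
#' that axis and +z, folded into [0, 90] degrees (axis sign ignored).
#'
#' @param coords N x 3 coordinate matrix (A).
#' @param sel_a,sel_b non-empty `selection`s defining the axis.
#' @return tilt angle in degrees.
#' @export
tilt_angle <- function(coords, sel_a, sel_b) {
  v <- geometric_center(coords, sel_b) - geometric_center(coords, sel_a)
  len <- sqrt(sum(v * v))
  if (len == 0) stop("coincident selection centers: tilt axis undefined")
  ang <- acos(min(1, abs(v[3]) / len)) * 180 / pi
  ang
}
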