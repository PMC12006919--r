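#' Write a particle system as a PQR file
#'
#' Free-format PQR: PDB-like ATOM records with per-atom charge (e) and
#' radius (A) in place of occupancy/B-factor. [read_structure()] on the
#' result recovers charges and radii.
#'
#' @param system a `particle_system`.
#' @param path output path.
#' @return invisibly, the path.
#' @export
write_pqr <- function(system, path) {
  at <- system$atoms
  coords <- get_coords(system)
  if (any(coords >= 1e4 | coords <= -1e3))
    stop("coordinate field overflow in PQR writer")
  nm <- as.character(at$name)
  nm <- ifelse(nchar(nm) < 4L, sprintf(" %-3s", nm), sprintf("%-4s", nm))
  lines <- sprintf("ATOM  %5d %s %-3s %1s%4d    %8.3f%8.3f%8.3f %7.4f %6.4f",
                   seq_len(nrow(at)) %% 100000L, nm,
                   substr(as.character(at$resname), 1, 3),
                   substr(as.character(at$chain), 1, 1), at$resid %% 10000L,
                   coords[, 1], coords[, 2], coords[, 3],
                   at$charge, at$radius)
  con <- file(path, "wt")
  on.exit(close(con))
  writeLines(c(lines, "END"), con)
  invisible(path)
}

# rigid rotation of coords about a center: axis-angle, angle in degrees
rotate_coords <- function(coords, axis, angle_deg, center = c(0, 0, 0)) {
  axis <- axis / sqrt(sum(axis^2))
  th <- angle_deg * pi / 180
  K <- matrix(c(0, axis[3], -axis[2],
                -axis[3], 0, axis[1],
                axis[2], -axis[1], 0), 3, 3)
  R <- diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
  sweep(sweep(coords, 2, center) %*% R, 2, center, "+")
}

mixed_resnames <- function(n) {
  cyc <- c("ALA", "LEU", "SER", "LYS", "VAL", "GLU", "THR", "ILE", "GLY", "ASN")
  rep_len(cyc, n)
}

build_fixture_system <- function(name, params = list()) {
  p <- function(key, default) params[[key]] %||% default
  switch(name,
    "linear-chain" = {
      n <- p("n", 10); spacing <- p("spacing", 5)
      sys <- particle_system(data.frame(
        name = "CA", resname = "GLY", resid = seq_len(n), chain = "A",
        x = (seq_len(n) - 1) * spacing, y = 0, z = 0), name = "linear-chain")
      list(system = assign_parameters(sys))
    },
    "two-lobe" = {
      # two 30-bead lobes joined by a hinge: a U-shaped elastic body with
      # mixed charges, the mechanical-deformation demo
      lobe <- function(center, chain, resid0) {
        pts <- sweep(golden_spiral_points(30) * 5.5, 2, center, "+")
        data.frame(name = "CA", resname = mixed_resnames(30),
                   resid = resid0 + seq_len(30) - 1L, chain = chain,
                   x = pts[, 1], y = pts[, 2], z = pts[, 3])
      }
      hinge <- data.frame(
        name = "CA", resname = "GLY", resid = 61:65, chain = "H",
        x = c(-6, -3, 0, 3, 6), y = 0, z = c(3.5, 2, 1.5, 2, 3.5))
      sys <- particle_system(
        rbind(lobe(c(-9, 0, 12), "A", 1L), lobe(c(9, 0, 12), "B", 31L), hinge),
        name = "two-lobe")
      sys <- assign_parameters(sys)
      # the hinge is the held region: anchoring it pins the rigid-motion
      # zero modes of the network, so a released deformation relaxes back
      # to the unmoved reference instead of a translated copy of it
      sys$atoms$dynamic[sys$atoms$chain == "H"] <- FALSE
      list(system = sys)
    },
    "dock-field" = {
      # static charged target ring + flexible charged 10-bead ligand chain
      # + an attraction grid whose global minimum marks the binding pose
      pose <- p("pose", c(0, 0, 2))
      ang <- 2 * pi * (0:11) / 12
      target <- data.frame(
        name = "CA", resname = "ASP", resid = 1:12, chain = "T",
        x = 5 * cos(ang), y = 5 * sin(ang), z = 0)
      lig_x <- (0:9) * 3 - 13.5
      ligand <- data.frame(
        name = "CA", resname = "LYS", resid = 13:22, chain = "L",
        x = pose[1] + lig_x, y = pose[2], z = pose[3] + 2)
      sys <- particle_system(rbind(target, ligand), name = "dock-field")
      sys <- assign_parameters(sys)
      sys$atoms$charge <- c(rep(-0.5, 12), rep(+0.5, 10))
      sys$atoms$dynamic <- c(rep(FALSE, 12), rep(TRUE, 10))
      # Gaussian potential well: the ligand beads carry +0.5 e, so q*phi is
      # lowest where phi is most negative. The grid's global value minimum
      # is the annotated pose, which sits exactly on a node.
      sp <- 2
      ax <- seq(-30, 30, by = sp)
      nx <- length(ax)
      phi <- array(0, dim = c(nx, nx, nx))
      for (k in seq_len(nx)) {
        d2 <- outer(ax - pose[1], ax - pose[2],
                    function(a, b) a^2 + b^2) + (ax[k] - pose[3])^2
        phi[, , k] <- -30 * exp(-d2 / (2 * 5^2))
      }
      grid <- scalar_grid(origin = c(-30, -30, -30), spacing = sp,
                          values = phi, mode = "potential")
      list(system = sys, grid = grid, pose = pose)
    },
    "membrane-barrel" = {
      # bead cylinder: hydrophobic belt (negative transfer energy) between
      # polar caps, pre-oriented along z and centred on the midplane
      n_ring <- p("beads_per_ring", 10)
      radius <- p("radius", 8)
      ring_z <- seq(-15, 15, by = 5)         # 7 rings, 30 A long
      belt <- abs(ring_z) <= 10              # rings 2..6 hydrophobic
      ang <- 2 * pi * (seq_len(n_ring) - 1) / n_ring
      rows <- do.call(rbind, lapply(seq_along(ring_z), function(r) {
        data.frame(name = "CA",
                   resname = if (belt[r]) "LEU" else "LYS",
                   resid = (r - 1L) * n_ring + seq_len(n_ring),
                   chain = "M",
                   x = radius * cos(ang + (r %% 2) * pi / n_ring),
                   y = radius * sin(ang + (r %% 2) * pi / n_ring),
                   z = ring_z[r])
      }))
      sys <- particle_system(rows, name = "membrane-barrel")
      sys <- assign_parameters(sys)
      sys$atoms$charge <- 0  # neutral barrel: the membrane term is the story
      # demo membrane: 24 A hydrophobic core with a soft ~3 A headgroup
      # interface, so a mis-oriented barrel still feels a usable gradient
      list(system = sys,
           membrane = membrane_model(center_z = 0, half_thickness = 12,
                                     interface_width = 3),
           top_ring = paste0("resid ", (length(ring_z) - 1) * n_ring + 1,
                             "..", length(ring_z) * n_ring),
           bottom_ring = paste0("resid 1..", n_ring))
    },
    stop("unknown fixture '", name, "'; available: linear-chain, two-lobe, ",
         "dock-field, membrane-barrel")
  )
}

#' Generate a self-contained demonstration system
#'
#' Deterministic generators for the systems used in tests and demos (no
#' downloads, no randomness):
#' \describe{
#'   \item{linear-chain}{n beads at fixed spacing along x; the unit-test
#'     substrate.}
#'   \item{two-lobe}{two 30-bead lobes joined by a hinge, a U-shaped
#'     elastic body with mixed charges; the mechanical-deformation demo.}
#'   \item{dock-field}{a static charged 12-bead target ring, a flexible
#'     charged 10-bead ligand chain, and an OpenDX attraction grid whose
#'     global value minimum sits exactly on the annotated binding pose;
#'     the guided-docking demo.}
#'   \item{membrane-barrel}{a bead cylinder with a hydrophobic belt
#'     (negative transfer energies) between polar caps, plus a membrane
#'     configuration; the membrane-insertion demo.}
#' }
#'
#' @param name fixture name (see above).
#' @param params named list of overrides (`n`, `spacing` for linear-chain;
#'   `pose` for dock-field; `beads_per_ring`, `radius` for membrane-barrel).
#' @param out_dir optional directory: when given, writes `<name>.pqr`, a
#'   copy of the parameter table, a ready-to-run `config.yaml` and (for
#'   dock-field) `field.dx`.
#' @return list with `system` (a `particle_system`) plus fixture-specific
#'   extras (`grid` and `pose` for dock-field; `top_ring`/`bottom_ring`
#'   selection strings for membrane-barrel; `files` when `out_dir` given).
#' @export
make_fixture <- function(name, params = list(), out_dir = NULL) {
  fx <- build_fixture_system(name, params)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    pqr <- file.path(out_dir, paste0(name, ".pqr"))
    write_pqr(fx$system, pqr)
    par_path <- file.path(out_dir, "parameters.csv")
    utils::write.csv(default_parameter_table(), par_path, row.names = FALSE,
                     quote = FALSE)
    cfg <- list(
      system = list(structure = paste0(name, ".pqr"),
                    parameters = "parameters.csv"),
      springs = list(list(cutoff = 9, stiffness = 0.6)),
      nonbonded = list(enabled = TRUE),
      dynamics = list(steps = 100, time_step = 5, damping = 0.2),
      output = list(trajectory = "trajectory.pdb",
                    observables = "observables.tsv", stride = 10))
    if (name == "dock-field") {
      dx <- file.path(out_dir, "field.dx")
      write_dx(fx$grid, dx)
      cfg$field <- list(file = "field.dx", mode = "potential", weight = 1)
      cfg$system$static <- "chain T"
      fx$files <- c(pqr = pqr, parameters = par_path, field = dx)
    }
    if (name == "membrane-barrel") {
      cfg$membrane <- list(center_z = 0, half_thickness = 12,
                           interface_width = 3, scale = 1,
                           depth_selection = "all",
                           tilt_a = fx$bottom_ring, tilt_b = fx$top_ring)
      cfg$dynamics <- list(integrator = "overdamped", mobility = 0.02,
                           time_step = 1, steps = 200)
    }
    cfg_path <- file.path(out_dir, "config.yaml")
    yaml::write_yaml(cfg, cfg_path)
    fx$files <- c(fx$files, config = cfg_path)
  }
  fx
}

#' Perturbed starting poses for the membrane-barrel demo
#'
#' Five rigidly transformed copies of the barrel coordinates: nominally
#' vertical, 30 and 60 degrees tilted, fully horizontal, and vertical but
#' displaced in depth. Each pose carries a small fixed symmetry-breaking
#' perturbation (a 2.5-degree rotation about a skew axis and a sub-A depth
#' offset) so that no start sits exactly on a saddle of the membrane
#' energy; the perturbations are constants, not random draws.
#'
#' @param coords the barrel's built N x 3 coordinates (axis along z,
#'   centred on the membrane midplane).
#' @return named list of five N x 3 coordinate matrices.
#' @export
barrel_poses <- function(coords) {
  center <- colMeans(coords)
  pose <- function(tilt, depth) {
    out <- rotate_coords(coords, c(0, 1, 0), tilt, center)
    # skew jitter axis: never parallel to the barrel axis at any nominal
    # tilt, so every pose (including exactly horizontal) is pushed off the
    # symmetry saddle of the membrane energy
    out <- rotate_coords(out, c(1, 1, 1), 2.5, center)
    out[, 3] <- out[, 3] + depth
    out
  }
  list(vertical = pose(0, 0.5),
       tilt30 = pose(30, -0.5),
       tilt60 = pose(60, 0.5),
       horizontal = pose(90, 1.0),
       displaced = pose(0, 5.0))
}
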