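#' Construct a regular scalar grid
#'
#' Regular 3D grid used for precomputed potential maps (kcal/mol/e in
#' `potential` mode) or density envelopes (arbitrary units in `density`
#' mode). Values are stored as an array indexed `[ix, iy, iz]`.
#'
#' @param origin length-3 vector (A), position of node (1,1,1).
#' @param spacing length-3 vector of positive grid spacings (A) (a scalar
#'   is recycled).
#' @param values 3D numeric array; all dimensions >= 2.
#' @param mode `"potential"` or `"density"`.
#' @return object of class `scalar_grid`.
#' @export
scalar_grid <- function(origin, spacing, values, mode = c("potential", "density")) {
  mode <- match.arg(mode)
  spacing <- rep_len(as.numeric(spacing), 3L)
  origin <- as.numeric(origin)
  stopifnot(length(origin) == 3L)
  if (any(spacing <= 0)) stop("grid spacing must be positive componentwise")
  if (length(dim(values)) != 3L) stop("values must be a 3D array")
  dims <- dim(values)
  if (any(dims < 2L)) stop("grid dimensions must all be >= 2")
  structure(list(origin = origin, spacing = spacing, dims = dims,
                 values = values, mode = mode),
            class = "scalar_grid")
}

#' @export
print.scalar_grid <- function(x, ...) {
  cat(sprintf("scalar_grid (%s): %d x %d x %d, spacing %.3g/%.3g/%.3g A\n",
              x$mode, x$dims[1], x$dims[2], x$dims[3],
              x$spacing[1], x$spacing[2], x$spacing[3]))
  invisible(x)
}

#' Read an OpenDX scalar grid (APBS dialect)
#'
#' Supports the "regular positions, regular connections" dialect with
#' diagonal `delta` records and z-fastest value ordering, as written by
#' Poisson-Boltzmann solvers.
#'
#' @param path OpenDX file.
#' @param mode interpretation of the values, `"potential"` or `"density"`.
#' @return a `scalar_grid`.
#' @export
read_dx <- function(path, mode = c("potential", "density")) {
  mode <- match.arg(mode)
  raw <- readLines(path, warn = FALSE)
  raw <- raw[!grepl("^[[:space:]]*#", raw)]
  gp <- grep("object.*class gridpositions counts", raw, value = TRUE)
  if (length(gp) != 1L) stop("not a regular OpenDX grid (gridpositions record missing)")
  dims <- as.integer(strsplit(trimws(sub(".*counts", "", gp[1])), "[[:space:]]+")[[1]])
  if (length(dims) != 3L || any(is.na(dims))) stop("malformed counts record")
  orig_line <- grep("^origin", raw, value = TRUE)
  if (length(orig_line) != 1L) stop("origin record missing")
  origin <- as.numeric(strsplit(trimws(sub("^origin", "", orig_line)), "[[:space:]]+")[[1]])
  deltas <- grep("^delta", raw, value = TRUE)
  if (length(deltas) != 3L) stop("expected exactly three delta records")
  dmat <- t(vapply(deltas, function(l)
    as.numeric(strsplit(trimws(sub("^delta", "", l)), "[[:space:]]+")[[1]]),
    numeric(3)))
  offdiag <- dmat; diag(offdiag) <- 0
  if (any(offdiag != 0)) stop("non-regular grid: delta records are not diagonal")
  spacing <- diag(dmat)
  data_at <- grep("data follows", raw)
  if (length(data_at) != 1L) stop("data section missing")
  tail_start <- grep("^(attribute|object \")", raw)
  tail_start <- tail_start[tail_start > data_at]
  last <- if (length(tail_start)) min(tail_start) - 1L else length(raw)
  vals <- as.numeric(unlist(strsplit(trimws(raw[(data_at + 1L):last]),
                                     "[[:space:]]+")))
  vals <- vals[!is.na(vals)]
  if (length(vals) != prod(dims))
    stop(sprintf("value count mismatch: %d values for %d x %d x %d grid",
                 length(vals), dims[1], dims[2], dims[3]))
  # z varies fastest in the file; convert to [ix, iy, iz] storage
  arr <- aperm(array(vals, dim = rev(dims)), c(3, 2, 1))
  scalar_grid(origin, spacing, arr, mode = mode)
}

#' Write a scalar grid as an OpenDX file
#'
#' Inverse of [read_dx()]: round-trips all header fields exactly and the
#' values at 6 significant digits.
#'
#' @param grid a `scalar_grid`.
#' @param path output path.
#' @return invisibly, the path.
#' @export
write_dx <- function(grid, path) {
  stopifnot(inherits(grid, "scalar_grid"))
  d <- grid$dims
  con <- file(path, "wt")
  on.exit(close(con))
  writeLines(c(
    sprintf("object 1 class gridpositions counts %d %d %d", d[1], d[2], d[3]),
    sprintf("origin %.6e %.6e %.6e", grid$origin[1], grid$origin[2], grid$origin[3]),
    sprintf("delta %.6e 0.000000e+00 0.000000e+00", grid$spacing[1]),
    sprintf("delta 0.000000e+00 %.6e 0.000000e+00", grid$spacing[2]),
    sprintf("delta 0.000000e+00 0.000000e+00 %.6e", grid$spacing[3]),
    sprintf("object 2 class gridconnections counts %d %d %d", d[1], d[2], d[3]),
    sprintf("object 3 class array type double rank 0 items %d data follows",
            prod(d))), con)
  vals <- as.vector(aperm(grid$values, c(3, 2, 1)))  # z fastest
  n3 <- (length(vals) %/% 3L) * 3L
  if (n3 > 0L) {
    m <- matrix(vals[seq_len(n3)], ncol = 3, byrow = TRUE)
    writeLines(sprintf("%.6e %.6e %.6e", m[, 1], m[, 2], m[, 3]), con)
  }
  if (n3 < length(vals))
    writeLines(paste(sprintf("%.6e", vals[(n3 + 1L):length(vals)]),
                     collapse = " "), con)
  writeLines(c('attribute "dep" string "positions"',
               'object "regular positions regular connections" class field',
               'component "positions" value 1',
               'component "connections" value 2',
               'component "data" value 3'), con)
  invisible(path)
}

#' Trilinear interpolation of a scalar grid
#'
#' Returns the trilinear value and its analytic gradient (constant per
#' cell per axis) at each query point. Points outside the grid hull are
#' clamped to the nearest boundary value and get a zero gradient, so
#' off-grid particles feel no field force.
#'
#' @param grid a `scalar_grid`.
#' @param points M x 3 matrix (or length-3 vector) of query points (A).
#' @return list with `value` (length M) and `gradient` (M x 3, per A).
#' @export
interpolate_grid <- function(grid, points) {
  stopifnot(inherits(grid, "scalar_grid"))
  if (is.null(dim(points))) points <- matrix(points, ncol = 3)
  points <- as_coord_matrix(points)
  m <- nrow(points)
  u <- sweep(sweep(points, 2, grid$origin), 2, grid$spacing, "/")
  hi <- grid$dims - 1L
  outside <- u[, 1] < 0 | u[, 2] < 0 | u[, 3] < 0 |
             u[, 1] > hi[1] | u[, 2] > hi[2] | u[, 3] > hi[3]
  for (a in 1:3) u[, a] <- pmin(pmax(u[, a], 0), hi[a])
  i0 <- pmin(floor(u), matrix(rep(hi - 1L, each = m), m, 3))
  t <- u - i0
  i0 <- i0 + 1L  # to 1-based node indices
  v <- grid$values
  corner <- function(dx, dy, dz)
    v[cbind(i0[, 1] + dx, i0[, 2] + dy, i0[, 3] + dz)]
  c000 <- corner(0, 0, 0); c100 <- corner(1, 0, 0)
  c010 <- corner(0, 1, 0); c110 <- corner(1, 1, 0)
  c001 <- corner(0, 0, 1); c101 <- corner(1, 0, 1)
  c011 <- corner(0, 1, 1); c111 <- corner(1, 1, 1)
  tx <- t[, 1]; ty <- t[, 2]; tz <- t[, 3]
  # interpolate x, then y, then z
  c00 <- c000 * (1 - tx) + c100 * tx
  c10 <- c010 * (1 - tx) + c110 * tx
  c01 <- c001 * (1 - tx) + c101 * tx
  c11 <- c011 * (1 - tx) + c111 * tx
  c0 <- c00 * (1 - ty) + c10 * ty
  c1 <- c01 * (1 - ty) + c11 * ty
  value <- c0 * (1 - tz) + c1 * tz
  gx <- ((c100 - c000) * (1 - ty) + (c110 - c010) * ty) * (1 - tz) +
        ((c101 - c001) * (1 - ty) + (c111 - c011) * ty) * tz
  gy <- ((c010 - c000) * (1 - tx) + (c110 - c100) * tx) * (1 - tz) +
        ((c011 - c001) * (1 - tx) + (c111 - c101) * tx) * tz
  gz <- ((c001 - c000) * (1 - tx) + (c101 - c100) * tx) * (1 - ty) +
        ((c011 - c010) * (1 - tx) + (c111 - c110) * tx) * ty
  gradient <- cbind(gx / grid$spacing[1], gy / grid$spacing[2],
                    gz / grid$spacing[3])
  gradient[outside, ] <- 0
  list(value = value, gradient = gradient)
}

#' Grid-field energy and forces on a particle cloud
#'
#' In `potential` mode the couplings are charges: `E_i = q_i phi(x_i)`,
#' `F_i = -q_i grad(phi)`. In `density` mode the couplings are fitting
#' weights and the energy is the linear pull `E_i = -w_i rho(x_i)`,
#' `F_i = +w_i grad(rho)`, attracting beads into high density. Particles
#' outside the grid hull contribute the clamped boundary value and feel
#' zero force.
#'
#' @param grid a `scalar_grid` (its `mode` decides the semantics).
#' @param coords N x 3 coordinate matrix (A).
#' @param couplings per-particle scalars (charges or weights).
#' @return list with `energy` and `forces` (N x 3).
#' @export
field_energy_forces <- function(grid, coords, couplings) {
  coords <- as_coord_matrix(coords)
  couplings <- rep_len(as.numeric(couplings), nrow(coords))
  ip <- interpolate_grid(grid, coords)
  if (grid$mode == "potential") {
    energy <- sum(couplings * ip$value)
    forces <- -couplings * ip$gradient
  } else {
    energy <- -sum(couplings * ip$value)
    forces <- couplings * ip$gradient
  }
  list(energy = energy, forces = forces)
}
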