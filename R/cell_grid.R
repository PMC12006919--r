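#' Build a cell grid for neighbour searches
#'
#' Axis-aligned grid of cubic cells covering the bounding box of the
#' coordinates; each particle belongs to exactly one cell, determined by
#' `floor((x - origin)/cell_size)`. The grid accelerates neighbour-pair
#' enumeration: a cutoff no larger than the cell size only requires
#' scanning the 27-cell neighbourhood.
#'
#' @param coords N x 3 coordinate matrix (A), all finite.
#' @param cell_size cell edge length (A), must be >= the largest
#'   interaction cutoff used with the grid.
#' @return object of class `cell_grid` with `origin`, `cell_size`, `dims`
#'   and per-cell member index lists.
#' @export
build_cell_grid <- function(coords, cell_size) {
  coords <- as_coord_matrix(coords)
  if (!all(is.finite(coords))) stop("non-finite coordinates")
  if (!is.numeric(cell_size) || length(cell_size) != 1L || cell_size <= 0)
    stop("cell_size must be a positive scalar")
  origin <- apply(coords, 2, min)
  ijk <- floor(sweep(coords, 2, origin) / cell_size)
  dims <- apply(ijk, 2, max) + 1L
  cid <- 1L + ijk[, 1] + dims[1] * (ijk[, 2] + dims[2] * ijk[, 3])
  cells <- split(seq_len(nrow(coords)), cid)
  structure(list(origin = origin, cell_size = cell_size, dims = dims,
                 cells = cells, cell_ijk = ijk, n = nrow(coords)),
            class = "cell_grid")
}

# canonical key for an unordered pair, used for exclusion lookups
pair_key <- function(i, j, n) {
  lo <- pmin(i, j); hi <- pmax(i, j)
  (lo - 1) * n + hi
}

#' Enumerate neighbour pairs from a cell grid
#'
#' All unordered pairs (i < j) with distance <= cutoff, found by scanning
#' each occupied cell's 27-cell neighbourhood, minus an optional exclusion
#' set (typically the spring pairs). The contract requires
#' `cutoff <= cell_size`, otherwise pairs could be missed.
#'
#' @param grid a `cell_grid` built from `coords`.
#' @param coords the same N x 3 matrix the grid was built from.
#' @param cutoff pair distance cutoff (A); ties at the cutoff are included.
#' @param exclusions optional 2-column matrix of particle index pairs to
#'   omit (order within a pair does not matter).
#' @return integer matrix with columns `i`, `j` (i < j), zero rows if none.
#' @export
neighbor_pairs <- function(grid, coords, cutoff, exclusions = NULL) {
  stopifnot(inherits(grid, "cell_grid"))
  coords <- as_coord_matrix(coords, grid$n)
  if (cutoff > grid$cell_size)
    stop("cutoff exceeds cell_size: neighbour enumeration would be incomplete")
  dims <- grid$dims
  cells <- grid$cells
  occupied <- as.numeric(names(cells))
  # decode cell ids back to (i,j,k)
  dec <- occupied - 1
  ci <- dec %% dims[1]; rem <- dec %/% dims[1]
  cj <- rem %% dims[2]; ck <- rem %/% dims[2]
  out_i <- integer(0); out_j <- integer(0)
  cid_of <- function(i, j, k) 1 + i + dims[1] * (j + dims[2] * k)
  cut2 <- cutoff * cutoff
  for (c_idx in seq_along(occupied)) {
    members <- cells[[c_idx]]
    # gather candidates from the 27-neighbourhood with cell id >= this cell
    cand <- integer(0)
    for (di in -1:1) for (dj in -1:1) for (dk in -1:1) {
      ni <- ci[c_idx] + di; nj <- cj[c_idx] + dj; nk <- ck[c_idx] + dk
      if (ni < 0 || nj < 0 || nk < 0 ||
          ni >= dims[1] || nj >= dims[2] || nk >= dims[3]) next
      nid <- cid_of(ni, nj, nk)
      if (nid < occupied[c_idx]) next    # that cell will scan us instead
      if (nid == occupied[c_idx]) next   # own cell handled below
      hit <- cells[[as.character(nid)]]
      if (!is.null(hit)) cand <- c(cand, hit)
    }
    # own-cell pairs
    if (length(members) > 1L) {
      cp <- utils::combn(members, 2L)
      out_i <- c(out_i, cp[1, ]); out_j <- c(out_j, cp[2, ])
    }
    if (length(cand)) {
      g <- expand.grid(i = members, j = cand)
      out_i <- c(out_i, g$i); out_j <- c(out_j, g$j)
    }
  }
  if (length(out_i) == 0L)
    return(matrix(integer(0), ncol = 2, dimnames = list(NULL, c("i", "j"))))
  i <- pmin(out_i, out_j); j <- pmax(out_i, out_j)
  d2 <- rowSums((coords[i, , drop = FALSE] - coords[j, , drop = FALSE])^2)
  keep <- d2 <= cut2
  i <- i[keep]; j <- j[keep]
  if (!is.null(exclusions) && nrow(exclusions) > 0L) {
    excl <- pair_key(exclusions[, 1], exclusions[, 2], grid$n)
    keep <- !(pair_key(i, j, grid$n) %in% excl)
    i <- i[keep]; j <- j[keep]
  }
  ord <- order(i, j)
  cbind(i = as.integer(i[ord]), j = as.integer(j[ord]))
}

# brute-force all-pairs enumeration; the independent oracle and the
# fallback used by builders on small systems
brute_force_pairs <- function(coords, cutoff, exclusions = NULL) {
  coords <- as_coord_matrix(coords)
  n <- nrow(coords)
  if (n < 2L)
    return(matrix(integer(0), ncol = 2, dimnames = list(NULL, c("i", "j"))))
  d <- as.matrix(stats::dist(coords))
  idx <- which(upper.tri(d) & d <= cutoff, arr.ind = TRUE)
  i <- idx[, 1]; j <- idx[, 2]
  if (!is.null(exclusions) && nrow(exclusions) > 0L) {
    excl <- pair_key(exclusions[, 1], exclusions[, 2], n)
    keep <- !(pair_key(i, j, n) %in% excl)
    i <- i[keep]; j <- j[keep]
  }
  ord <- order(i, j)
  cbind(i = as.integer(i[ord]), j = as.integer(j[ord]))
}
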