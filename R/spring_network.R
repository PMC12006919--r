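#' Build a Hookean spring network from a structure
#'
#' A spring is created for every particle pair whose initial distance is
#' within the cutoff (ties at exactly the cutoff are included); the rest
#' length of each spring is that initial distance, so the input structure
#' is by construction the energy minimum of the network. A single uniform
#' stiffness is used for all springs of a layer. `within` restricts the
#' network to pairs inside one selection; `between` restricts it to pairs
#' bridging two selections (e.g. a soft inter-domain layer).
#'
#' @param system a `particle_system`.
#' @param cutoff spring cutoff distance (A); the commonly used range is
#'   7-15 A, default 9.
#' @param stiffness uniform force constant K (kcal/mol/A^2), default 0.6.
#'   Note the energy convention `K*(d - d0)^2` with no 1/2 prefactor.
#' @param within optional `selection`: both partners must be members.
#' @param between optional list of two `selection`s: one partner in each.
#' @param layer label for this layer.
#' @return object of class `spring_network`: list with `springs`
#'   (data.frame `i`, `j`, `stiffness`, `rest_length`, with i < j),
#'   `cutoff_used`, `layer_label` and `n` (system size).
#' @export
#' @examples
#' ps <- particle_system(data.frame(name = "CA", resname = "GLY",
#'   resid = 1:3, chain = "A", x = c(0, 5, 10), y = 0, z = 0))
#' build_springs(ps, cutoff = 7)$springs
build_springs <- function(system, cutoff = 9, stiffness = 0.6,
                          within = NULL, between = NULL, layer = "layer1") {
  stopifnot(inherits(system, "particle_system"))
  if (!is.numeric(cutoff) || cutoff <= 0) stop("cutoff must be > 0")
  if (!is.numeric(stiffness) || stiffness <= 0) stop("stiffness must be > 0")
  coords <- get_coords(system)
  n <- nrow(coords)
  pairs <- if (n > 200L) {
    grid <- build_cell_grid(coords, cell_size = cutoff)
    neighbor_pairs(grid, coords, cutoff)
  } else brute_force_pairs(coords, cutoff)
  if (!is.null(within)) {
    check_selection(within, n)
    keep <- pairs[, 1] %in% within$indices & pairs[, 2] %in% within$indices
    pairs <- pairs[keep, , drop = FALSE]
  }
  if (!is.null(between)) {
    stopifnot(is.list(between), length(between) == 2L)
    a <- check_selection(between[[1]], n)$indices
    b <- check_selection(between[[2]], n)$indices
    keep <- (pairs[, 1] %in% a & pairs[, 2] %in% b) |
            (pairs[, 1] %in% b & pairs[, 2] %in% a)
    pairs <- pairs[keep, , drop = FALSE]
  }
  d0 <- sqrt(rowSums((coords[pairs[, 1], , drop = FALSE] -
                      coords[pairs[, 2], , drop = FALSE])^2))
  if (any(d0 == 0))
    stop("coincident particles: a spring pair has zero initial distance")
  springs <- data.frame(i = pairs[, 1], j = pairs[, 2],
                        stiffness = stiffness, rest_length = d0)
  structure(list(springs = springs, cutoff_used = cutoff,
                 layer_label = layer, n = n),
            class = "spring_network")
}

#' Merge several spring layers into one network
#'
#' Union of the layers' springs. A pair present in several layers keeps
#' the entry from the earliest layer (first-layer-wins), so a stiff
#' backbone layer declared first is protected from being overwritten by
#' later soft layers. (The alternative convention, summing stiffnesses, is
#' not used.)
#'
#' @param layers list of `spring_network` objects over the same system.
#' @return a merged `spring_network`.
#' @export
merge_layers <- function(layers) {
  stopifnot(is.list(layers), length(layers) >= 1L)
  for (l in layers) stopifnot(inherits(l, "spring_network"))
  n <- unique(vapply(layers, function(l) l$n, numeric(1)))
  if (length(n) != 1L)
    stop("layers reference systems of different sizes")
  all_springs <- do.call(rbind, lapply(layers, function(l) l$springs))
  key <- paste(all_springs$i, all_springs$j)
  merged <- all_springs[!duplicated(key), , drop = FALSE]
  merged <- merged[order(merged$i, merged$j), , drop = FALSE]
  rownames(merged) <- NULL
  structure(list(springs = merged,
                 cutoff_used = max(vapply(layers, function(l) l$cutoff_used,
                                          numeric(1))),
                 layer_label = paste(vapply(layers, function(l) l$layer_label,
                                            character(1)), collapse = "+"),
                 n = n),
            class = "spring_network")
}

#' @export
print.spring_network <- function(x, ...) {
  cat(sprintf("spring_network '%s': %d springs, cutoff %.2f A\n",
              x$layer_label, nrow(x$springs), x$cutoff_used))
  invisible(x)
}

#' Spring energy and forces
#'
#' Evaluates the harmonic network energy `V = sum_{i<j} K (d_ij - d0_ij)^2`
#' (no 1/2 prefactor; K follows that convention) and its analytic forces:
#' the force on i is `-2K(d - d0) (r_i - r_j)/d`, equal and opposite on j.
#'
#' @param net a `spring_network`.
#' @param coords N x 3 coordinate matrix (A).
#' @return list with `energy` (kcal/mol) and `forces` (N x 3, kcal/mol/A).
#' @export
spring_energy_forces <- function(net, coords) {
  stopifnot(inherits(net, "spring_network"))
  coords <- as_coord_matrix(coords, net$n)
  sp <- net$springs
  if (nrow(sp) == 0L)
    return(list(energy = 0, forces = matrix(0, net$n, 3)))
  dr <- coords[sp$i, , drop = FALSE] - coords[sp$j, , drop = FALSE]
  d <- sqrt(rowSums(dr * dr))
  if (any(d == 0))
    stop("coincident bonded pair: spring gradient undefined at zero distance")
  dev <- d - sp$rest_length
  energy <- sum(sp$stiffness * dev * dev)
  fmag <- -2 * sp$stiffness * dev / d           # along (r_i - r_j)
  fi <- dr * fmag
  forces <- accumulate_forces(net$n, sp$i, sp$j, fi)
  list(energy = energy, forces = forces)
}

# scatter-add pair forces: +contrib on i, -contrib on j
accumulate_forces <- function(n, i, j, contrib) {
  forces <- matrix(0, n, 3)
  stacked <- rbind(contrib, -contrib)
  idx <- c(i, j)
  s <- rowsum(stacked, group = idx)
  rows <- as.integer(rownames(s))
  forces[rows, ] <- forces[rows, ] + s
  forces
}

#' Serialize a spring network to a delimited text file
#'
#' Header comment records the cutoff and layer label; columns are
#' `i,j,stiffness,rest_length`. [read_spring_network()] restores the
#' network bit-exactly (values are written with full precision).
#'
#' @param net a `spring_network`.
#' @param path output path.
#' @return invisibly, the path.
#' @export
write_spring_network <- function(net, path) {
  con <- file(path, "wt")
  on.exit(close(con))
  writeLines(sprintf("# cutoff=%s layer=%s n=%d",
                     format(net$cutoff_used, digits = 17),
                     net$layer_label, net$n), con)
  writeLines("i,j,stiffness,rest_length", con)
  sp <- net$springs
  writeLines(sprintf("%d,%d,%s,%s", sp$i, sp$j,
                     format(sp$stiffness, digits = 17),
                     format(sp$rest_length, digits = 17)), con)
  invisible(path)
}

#' Read a spring network written by [write_spring_network()]
#' @param path input path.
#' @return a `spring_network`.
#' @export
read_spring_network <- function(path) {
  raw <- readLines(path, warn = FALSE)
  hd <- raw[1]
  if (!grepl("^# cutoff=", hd)) stop("not a spring network file: ", path)
  cutoff <- as.numeric(sub("^# cutoff=([^ ]+).*", "\\1", hd))
  layer <- sub("^.* layer=([^ ]+).*", "\\1", hd)
  n <- as.integer(sub("^.* n=([0-9]+).*", "\\1", hd))
  sp <- utils::read.csv(text = raw[-1], stringsAsFactors = FALSE)
  structure(list(springs = sp, cutoff_used = cutoff, layer_label = layer,
                 n = n),
            class = "spring_network")
}

# 2-column matrix of spring pairs, for non-bonded exclusions
spring_pairs <- function(net) {
  cbind(i = net$springs$i, j = net$springs$j)
}
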