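#' Select particles with a mini expression grammar
#'
#' The grammar supports the primitives `all`, `index i..j` (or a single
#' `index i`), `chain X`, `resid i..j` (or `resid i`) and `name CA`, which
#' can be combined with `and` (intersection, binds tighter) and `or`
#' (union). Particle indices are 1-based, matching R convention and PDB
#' serials.
#'
#' @param system a `particle_system`.
#' @param expression selection string, e.g. `"chain A and name CA"`.
#' @return Object of class `selection`: list with sorted unique `indices`
#'   and the `source_expression`. A selection may be empty; operations
#'   that require particles reject empty selections.
#' @export
#' @examples
#' ps <- particle_system(data.frame(
#'   name = c("CA", "CB", "CA"), resname = "ALA", resid = 1:3,
#'   chain = c("A", "A", "B"), x = 0, y = 0, z = 1:3))
#' select_particles(ps, "name CA")$indices
#' select_particles(ps, "chain A or index 3")$indices
select_particles <- function(system, expression) {
  stopifnot(inherits(system, "particle_system"))
  toks <- strsplit(trimws(expression), "[[:space:]]+")[[1]]
  if (length(toks) == 0L || identical(toks, ""))
    stop("empty selection expression")
  st <- new.env(parent = emptyenv())
  st$toks <- toks
  st$pos <- 1L
  idx <- parse_or(st, system)
  if (st$pos <= length(st$toks))
    stop(sprintf("selection syntax error at token %d ('%s')",
                 st$pos, st$toks[st$pos]))
  structure(list(indices = sort(unique(idx)),
                 source_expression = expression),
            class = "selection")
}

peek_tok <- function(st) if (st$pos <= length(st$toks)) st$toks[st$pos] else NA_character_
take_tok <- function(st) { t <- peek_tok(st); st$pos <- st$pos + 1L; t }

parse_or <- function(st, system) {
  idx <- parse_and(st, system)
  while (identical(peek_tok(st), "or")) {
    take_tok(st)
    idx <- union(idx, parse_and(st, system))
  }
  idx
}

parse_and <- function(st, system) {
  idx <- parse_primary(st, system)
  while (identical(peek_tok(st), "and")) {
    take_tok(st)
    idx <- intersect(idx, parse_primary(st, system))
  }
  idx
}

parse_range <- function(tok, what, pos) {
  m <- regmatches(tok, regexec("^(-?[0-9]+)(\\.\\.(-?[0-9]+))?$", tok))[[1]]
  if (length(m) == 0L)
    stop(sprintf("selection syntax error at token %d: expected %s number or i..j, got '%s'",
                 pos, what, tok))
  lo <- as.integer(m[2])
  hi <- if (nzchar(m[4])) as.integer(m[4]) else lo
  c(lo, hi)
}

parse_primary <- function(st, system) {
  tok <- take_tok(st)
  if (is.na(tok))
    stop(sprintf("selection syntax error at token %d: unexpected end of expression", st$pos - 1L))
  at <- system$atoms
  switch(tok,
    "all" = seq_len(nrow(at)),
    "index" = {
      r <- parse_range(take_tok(st), "index", st$pos - 1L)
      bad <- r[r < 1L | r > nrow(at)]
      if (length(bad))
        stop("index out of range: ", paste(bad, collapse = ", "))
      seq.int(r[1], r[2])
    },
    "resid" = {
      r <- parse_range(take_tok(st), "resid", st$pos - 1L)
      which(at$resid >= r[1] & at$resid <= r[2])
    },
    "chain" = {
      v <- take_tok(st)
      if (is.na(v)) stop("selection syntax error: 'chain' needs an argument")
      which(at$chain == v)
    },
    "name" = {
      v <- take_tok(st)
      if (is.na(v)) stop("selection syntax error: 'name' needs an argument")
      which(at$name == v)
    },
    stop(sprintf("selection syntax error at token %d ('%s')", st$pos - 1L, tok))
  )
}

#' @export
print.selection <- function(x, ...) {
  cat(sprintf("selection '%s': %d particles\n",
              x$source_expression, length(x$indices)))
  invisible(x)
}

is_empty_selection <- function(sel) length(sel$indices) == 0L

check_selection <- function(sel, n, allow_empty = FALSE) {
  stopifnot(inherits(sel, "selection"))
  if (!allow_empty && is_empty_selection(sel))
    stop(sprintf("selection '%s' matches no particles", sel$source_expression))
  if (length(sel$indices) && (min(sel$indices) < 1L || max(sel$indices) > n))
    stop("selection indices out of range for this system")
  invisible(sel)
}

#' Geometric center of a selection
#'
#' Unweighted mean position of the selected particles.
#'
#' @param coords N x 3 coordinate matrix (A).
#' @param sel a non-empty `selection` (default: all rows).
#' @return length-3 numeric vector (A).
#' @export
geometric_center <- function(coords, sel = NULL) {
  coords <- as_coord_matrix(coords)
  idx <- if (is.null(sel)) seq_len(nrow(coords)) else {
    check_selection(sel, nrow(coords))
    sel$indices
  }
  unname(colMeans(coords[idx, , drop = FALSE]))
}

#' Coordinate RMSD over a selection
#'
#' Root-mean-square displacement between two coordinate sets with no
#' least-squares superposition: relaxation experiments compare a perturbed
#' state against the unmoved reference, so fitting is deliberately not
#' performed (use [bio3d::fit.xyz()] if you need fitted RMSD).
#'
#' @param coordsA,coordsB N x 3 coordinate matrices over the same particles.
#' @param sel optional `selection`; default all particles.
#' @return non-negative scalar (A); zero iff the selected coordinates are
#'   identical.
#' @export
coord_rmsd <- function(coordsA, coordsB, sel = NULL) {
  coordsA <- as_coord_matrix(coordsA)
  coordsB <- as_coord_matrix(coordsB, nrow(coordsA))
  idx <- if (is.null(sel)) seq_len(nrow(coordsA)) else {
    check_selection(sel, nrow(coordsA))
    sel$indices
  }
  d <- coordsA[idx, , drop = FALSE] - coordsB[idx, , drop = FALSE]
  sqrt(mean(rowSums(d * d)))
}
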