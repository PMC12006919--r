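#' Read a structure file into a particle system
#'
#' Reads PDB (column-strict, via bio3d) or PQR (whitespace-tokenized, the
#' PQR dialect is not column-strict) files. PQR per-atom charge (e) and
#' radius (A) are captured; for plain PDB input charge and radius default
#' to zero until [assign_parameters()] fills them in. Epsilon, mass and
#' transfer energy always start as zero placeholders. Multi-model files
#' are truncated to the first model with a warning.
#'
#' @param path file path; format chosen by extension (`.pqr` = PQR,
#'   anything else = PDB).
#' @param name system label (default: file base name).
#' @return a `particle_system`.
#' @export
read_structure <- function(path, name = NULL) {
  if (!file.exists(path)) stop("structure file not found: ", path)
  is_pqr <- grepl("\\.pqr$", path, ignore.case = TRUE)
  raw <- readLines(path, warn = FALSE)
  if (!any(grepl("^(ATOM|HETATM)", raw)))
    stop("no atoms: file contains no ATOM/HETATM records: ", path)
  if (sum(grepl("^MODEL", raw)) > 1L)
    warning("multi-model input: keeping the first model only")
  pdb <- tryCatch(
    if (is_pqr) bio3d::read.pqr(path, multi = FALSE)
    else bio3d::read.pdb(path, multi = FALSE, verbose = FALSE),
    error = function(e) stop("could not parse structure file '", path,
                             "': ", conditionMessage(e), call. = FALSE))
  at <- pdb$atom
  if (any(!is.finite(at$x)) || any(!is.finite(at$y)) || any(!is.finite(at$z)))
    stop("malformed coordinate field in ", path)
  chain <- at$chain
  chain[is.na(chain)] <- "A"
  atoms <- data.frame(
    name = at$elety,
    resname = at$resid,
    resid = at$resno,
    chain = chain,
    x = at$x, y = at$y, z = at$z,
    charge = if (is_pqr) ifelse(is.na(at$o), 0, at$o) else 0,
    radius = if (is_pqr) ifelse(is.na(at$b), 0, at$b) else 0,
    epsilon = 0, mass = 0, transfer_energy = 0, dynamic = TRUE,
    stringsAsFactors = FALSE)
  if (is.null(name))
    name <- sub("\\.[^.]*$", "", basename(path))
  particle_system(atoms, name = name)
}

#' Write a particle system as a single-frame PDB file
#'
#' @param system a `particle_system`.
#' @param path output path.
#' @param coords optional N x 3 matrix overriding the stored coordinates.
#' @return invisibly, the path.
#' @export
write_structure <- function(system, path, coords = NULL) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  if (is.null(coords)) coords <- get_coords(system)
  write_pdb_atoms(con, system, coords)
  writeLines("END", con)
  invisible(path)
}

#' Append one trajectory frame to an open connection
#'
#' Writes a MODEL/ENDMDL-delimited PDB frame with fixed-width (%8.3f)
#' coordinates, so [read_structure()] on any single frame reproduces the
#' coordinates to 3 decimals. Coordinates that do not fit the fixed-width
#' field raise an error rather than being silently truncated.
#'
#' @param con open writable connection.
#' @param system a `particle_system`.
#' @param coords N x 3 coordinate matrix (A).
#' @param frame 1-based frame counter written to the MODEL record.
#' @return invisibly, `frame`.
#' @export
write_trajectory_frame <- function(con, system, coords, frame) {
  stopifnot(inherits(con, "connection"))
  coords <- as_coord_matrix(coords, n_particles(system))
  writeLines(sprintf("MODEL     %4d", as.integer(frame)), con)
  write_pdb_atoms(con, system, coords)
  writeLines("ENDMDL", con)
  invisible(frame)
}

write_pdb_atoms <- function(con, system, coords) {
  if (any(coords >= 1e4 | coords <= -1e3))
    stop("coordinate field overflow: a coordinate does not fit the PDB %8.3f field")
  at <- system$atoms
  n <- nrow(at)
  nm <- as.character(at$name)
  # wwPDB name layout: <4 char names start in column 14
  nm <- ifelse(nchar(nm) < 4L, sprintf(" %-3s", nm), sprintf("%-4s", nm))
  lines <- sprintf("ATOM  %5d %s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f",
                   seq_len(n) %% 100000L, nm,
                   substr(as.character(at$resname), 1, 3),
                   substr(as.character(at$chain), 1, 1),
                   at$resid %% 10000L,
                   coords[, 1], coords[, 2], coords[, 3],
                   1.0, 0.0)
  writeLines(lines, con)
}

#' Read a multi-frame PDB trajectory written by this package
#'
#' @param path trajectory file with MODEL/ENDMDL frames.
#' @return list of N x 3 coordinate matrices, one per frame.
#' @export
read_trajectory <- function(path) {
  raw <- readLines(path, warn = FALSE)
  starts <- grep("^MODEL", raw)
  ends <- grep("^ENDMDL", raw)
  if (length(starts) == 0L) { starts <- 1L; ends <- length(raw) }
  if (length(starts) != length(ends))
    stop("unbalanced MODEL/ENDMDL records in ", path)
  lapply(seq_along(starts), function(k) {
    blk <- raw[starts[k]:ends[k]]
    blk <- blk[grepl("^(ATOM|HETATM)", blk)]
    m <- cbind(as.numeric(substr(blk, 31, 38)),
               as.numeric(substr(blk, 39, 46)),
               as.numeric(substr(blk, 47, 54)))
    if (any(!is.finite(m))) stop("malformed coordinate field in frame ", k)
    colnames(m) <- c("x", "y", "z")
    m
  })
}
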