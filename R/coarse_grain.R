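AMINO3 <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS",
            "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP",
            "TYR", "VAL")
NUC_RES <- c("DA", "DC", "DG", "DT", "A", "C", "G", "U", "T")

#' Reduce an all-atom system to one bead per residue
#'
#' Each residue, identified by (chain, resid), becomes a single bead placed
#' at its representative atom: CA for amino acids, P for nucleotides. The
#' bead charge and mass are the sums over the residue's member atoms, so
#' total charge and mass are conserved exactly; radius and epsilon are left
#' for [assign_parameters()]. Residues lacking their representative atom
#' are skipped and listed in the `skipped` attribute of the result.
#'
#' @param system a `particle_system` (typically all-atom).
#' @param scheme `"calpha-trace"` (CA for every residue), `"p-trace"` (P),
#'   or `"auto"` (per residue type: P for nucleotides, CA otherwise).
#' @return a `particle_system` of beads, with attribute `skipped`
#'   (data.frame of residues without a representative atom).
#' @export
#' @examples
#' # a 1-residue, 2-atom toy: bead sits on the CA, charge is summed
#' ps <- particle_system(data.frame(
#'   name = c("N", "CA"), resname = "ALA", resid = 1, chain = "A",
#'   x = c(0, 1), y = 0, z = 0, charge = c(-0.3, 0.1)))
#' coarse_grain(ps)$atoms[, c("x", "charge")]
coarse_grain <- function(system, scheme = c("auto", "calpha-trace", "p-trace")) {
  scheme <- match.arg(scheme)
  at <- system$atoms
  key <- paste(at$chain, at$resid, sep = "\r")
  groups <- split(seq_len(nrow(at)), factor(key, levels = unique(key)))
  beads <- vector("list", length(groups))
  skipped <- list()
  for (k in seq_along(groups)) {
    rows <- groups[[k]]
    res <- at[rows, , drop = FALSE]
    rep_name <- switch(scheme,
      "calpha-trace" = "CA",
      "p-trace" = "P",
      "auto" = if (res$resname[1] %in% NUC_RES) "P" else "CA")
    hit <- which(res$name == rep_name)
    if (length(hit) == 0L) {
      skipped[[length(skipped) + 1L]] <- data.frame(
        chain = res$chain[1], resid = res$resid[1],
        resname = res$resname[1], missing = rep_name)
      next
    }
    r <- hit[1]
    beads[[k]] <- data.frame(
      name = rep_name, resname = res$resname[1], resid = res$resid[1],
      chain = res$chain[1], x = res$x[r], y = res$y[r], z = res$z[r],
      charge = sum(res$charge), radius = 0, epsilon = 0,
      mass = sum(res$mass), transfer_energy = 0,
      dynamic = res$dynamic[r], stringsAsFactors = FALSE)
  }
  beads <- beads[!vapply(beads, is.null, logical(1))]
  if (length(beads) == 0L)
    stop("coarse graining produced no beads (no residue has its representative atom)")
  out <- particle_system(do.call(rbind, beads),
                         name = paste0(system$name, "-cg"))
  attr(out, "skipped") <- if (length(skipped)) do.call(rbind, skipped)
    else data.frame(chain = character(), resid = integer(),
                    resname = character(), missing = character())
  out
}
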