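#' Read atomic coordinates from a PDB or mmCIF file
#'
#' Positions are returned in Angstrom with an occupancy-derived weight;
#' records that are neither ATOM nor (optionally) HETATM are skipped and
#' counted in a message.
#'
#' @param path coordinate file (`.pdb` or `.cif`).
#' @param ca_only keep only C-alpha atoms (coarse rasterization).
#' @param include_het include HETATM records.
#' @param center subtract the centroid so positions are relative to the
#'   model center (convenient for [model_to_map()]).
#' @return data.frame with `x`, `y`, `z`, `weight`, `elety`, `resid`,
#'   `chain`.
#' @export
read_coordinates <- function(path, ca_only = FALSE, include_het = TRUE,
                             center = FALSE) {
  if (!file.exists(path)) stop("no such coordinate file: ", path)
  is_cif <- grepl("\\.cif$", path, ignore.case = TRUE)
  pdb <- if (is_cif) bio3d::read.cif(path) else
    suppressWarnings(bio3d::read.pdb(path))
  at <- pdb$atom
  n_all <- nrow(at)
  if (!include_het) at <- at[at$type == "ATOM", , drop = FALSE]
  if (ca_only) at <- at[at$elety == "CA", , drop = FALSE]
  skipped <- n_all - nrow(at)
  if (skipped > 0) message(skipped, " atom records skipped")
  if (nrow(at) == 0L) stop("no atoms read from ", path)
  w <- at$o
  w[is.na(w)] <- 1
  out <- data.frame(x = at$x, y = at$y, z = at$z, weight = w,
                    elety = at$elety, resid = at$resid,
                    chain = at$chain, stringsAsFactors = FALSE)
  if (center) {
    out$x <- out$x - mean(out$x)
    out$y <- out$y - mean(out$y)
    out$z <- out$z - mean(out$z)
  }
  out
}
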