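# Pairwise Euclidean cross-distances between two coordinate matrices.
cross_dist <- function(a, b) {
  d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * a %*% t(b)
  sqrt(pmax(d2, 0))
}

#' Per-residue minimum heavy-atom distance to each bound ligand
#'
#' For every polymer residue in the structure, computes the minimum distance
#' between any of its heavy atoms and any heavy atom of any copy of each
#' named HETATM ligand, in any chain. Cross-chain proximity counts: a
#' residue close to the ligand bound in the partner subunit of a dimer gets
#' that (smaller) distance.
#'
#' @param pdb a `bio3d` `pdb` object ([read_structure()]), or a file path /
#'   PDB text vector which will be parsed.
#' @param ligands character vector of HET residue codes (default
#'   `c("IPM", "NAD")`, the substrate and coenzyme of IPMDH).
#' @return data frame of class `residue_distance_map` with one row per
#'   residue: `chain`, `resno`, `resname`, one `dist_<ligand>` column per
#'   ligand, and `min_dist` (minimum over ligands).
#' @export
compute_distance_map <- function(pdb, ligands = c("IPM", "NAD")) {
  if (!inherits(pdb, "pdb")) pdb <- read_structure(pdb)
  at <- pdb$atom
  heavy <- is.na(at$elesy) | toupper(trimws(at$elesy)) != "H"
  prot <- at$type == "ATOM" & heavy
  if (!any(prot)) stop("structure contains no protein ATOM records")

  lig_coords <- lapply(ligands, function(lg) {
    sel <- at$type == "HETATM" & at$resid == lg & heavy
    if (!any(sel)) {
      avail <- unique(at$resid[at$type == "HETATM"])
      stop("ligand '", lg, "' not found; available HET groups: ",
           if (length(avail)) paste(avail, collapse = ", ") else "(none)")
    }
    as.matrix(at[sel, c("x", "y", "z")])
  })
  names(lig_coords) <- ligands

  pa <- at[prot, ]
  res_key <- paste(pa$chain, pa$resno, pa$resid, sep = "|")
  keys <- unique(res_key)
  pcoord <- as.matrix(pa[, c("x", "y", "z")])

  dist_cols <- lapply(lig_coords, function(lc) {
    dmin <- apply(cross_dist(pcoord, lc), 1, min)
    as.numeric(tapply(dmin, factor(res_key, levels = keys), min))
  })

  parts <- strsplit(keys, "|", fixed = TRUE)
  out <- data.frame(
    chain = vapply(parts, `[`, "", 1),
    resno = as.integer(vapply(parts, `[`, "", 2)),
    resname = vapply(parts, `[`, "", 3),
    stringsAsFactors = FALSE)
  for (lg in ligands) out[[paste0("dist_", lg)]] <- dist_cols[[lg]]
  out$min_dist <- do.call(pmin, dist_cols)
  out <- out[order(out$chain, out$resno), ]
  rownames(out) <- NULL
  class(out) <- c("residue_distance_map", "data.frame")
  attr(out, "ligands") <- ligands
  out
}

# Minimum heavy-atom distance between two residues (all chains, all copies
# of the residue number are taken together when `chain` is NA).
residue_pair_min_dist <- function(pdb, resno_a, resno_b,
                                  chain_a = NA, chain_b = NA) {
  at <- pdb$atom
  heavy <- is.na(at$elesy) | toupper(trimws(at$elesy)) != "H"
  sel_a <- at$type == "ATOM" & heavy & at$resno == resno_a &
    (is.na(chain_a) | at$chain == chain_a)
  sel_b <- at$type == "ATOM" & heavy & at$resno == resno_b &
    (is.na(chain_b) | at$chain == chain_b)
  if (!any(sel_a) || !any(sel_b)) return(NA_real_)
  min(cross_dist(as.matrix(at[sel_a, c("x", "y", "z")]),
                 as.matrix(at[sel_b, c("x", "y", "z")])))
}
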