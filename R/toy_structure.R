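# Fixed-width PDB v3.3 ATOM/HETATM record.
pdb_record <- function(rec, serial, name, resname, chain, resno, xyz,
                       element) {
  name_fmt <- if (nchar(name) < 4) sprintf(" %-3s", name) else name
  sprintf("%-6s%5d %4s%1s%3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          rec, serial, name_fmt, "", resname, chain, resno, "",
          xyz[1], xyz[2], xyz[3], 1.00, 0.00, element)
}

# Quasi-uniform unit vectors (Fibonacci sphere), deterministic in i.
fib_direction <- function(i, n = max(i) + 8) {
  golden <- (1 + sqrt(5)) / 2
  z <- 1 - 2 * (i - 0.5) / n
  r <- sqrt(pmax(0, 1 - z^2))
  phi <- 2 * pi * i / golden
  cbind(r * cos(phi), r * sin(phi), z)
}

#' Build a toy ligand-bound structure with controlled contact distances
#'
#' Emits PDB-format text for a minimal protein in which each residue's
#' minimum heavy-atom distance to the bound ligands equals a requested
#' target. Each residue carries a backbone (N, CA, C, O) plus one side-chain
#' pseudo-atom (CB) placed closest to the ligand; each ligand copy is a
#' three-atom HETATM cluster. Used to exercise the distance-shell mutation
#' site selection rules without downloading a crystal structure.
#'
#' @param sites data frame with columns `chain`, `resno` (unique per chain),
#'   `resname` (3-letter code) and `dist` (target minimum heavy-atom distance
#'   to the ligand set, Angstrom, >= ~1). Optional columns: `ligand` (name of
#'   the copy to anchor to; default nearest is the first copy) and
#'   `dx`,`dy`,`dz` (placement direction; default quasi-uniform).
#' @param ligands data frame describing ligand copies with columns `name`
#'   (HET code), `chain`, `x`, `y`, `z` (cluster centre). The default places
#'   one IPM and one NAD copy 3 Angstrom apart.
#' @return character vector of PDB lines (class `toy_structure`), suitable
#'   for `writeLines()` and parsing with `bio3d::read.pdb()`.
#' @details Placement is solved by 1-d root finding along a ray pointing
#'   away from all ligand copies; the achieved minimum distance is verified
#'   against the target to 0.01 Angstrom and clashing or unreachable
#'   placements are reported as errors.
#' @export
#' @examples
#' s <- make_toy_structure(data.frame(chain = "A", resno = 10,
#'                                    resname = "VAL", dist = 5))
make_toy_structure <- function(sites,
                               ligands = data.frame(
                                 name = c("IPM", "NAD"),
                                 chain = c("A", "A"),
                                 x = c(0, 3), y = c(0, 0), z = c(0, 0))) {
  stopifnot(all(c("chain", "resno", "resname", "dist") %in% names(sites)),
            all(c("name", "chain", "x", "y", "z") %in% names(ligands)),
            nrow(ligands) >= 1)
  if (any(sites$dist <= 0)) stop("target distances must be positive")
  key <- paste(sites$chain, sites$resno)
  if (anyDuplicated(key)) stop("residue numbers must be unique per chain")

  cluster_offsets <- rbind(c(0, 0, 0), c(0.5, 0.3, 0), c(-0.3, 0.4, 0.3))
  centres <- as.matrix(ligands[, c("x", "y", "z")])
  lig_atoms <- do.call(rbind, lapply(seq_len(nrow(ligands)), function(k) {
    sweep(cluster_offsets, 2, centres[k, ], "+")
  }))

  min_dist_to_ligands <- function(p) {
    min(sqrt(rowSums(sweep(lig_atoms, 2, p, "-")^2)))
  }

  dirs <- fib_direction(seq_len(nrow(sites)), n = nrow(sites) + 8)
  atom_offsets <- c(CB = 0, CA = 1.2, N = 2.0, C = 2.8, O = 3.6)
  atom_elems <- c(CB = "C", CA = "C", N = "N", C = "C", O = "O")

  placed <- vector("list", nrow(sites))
  for (i in seq_len(nrow(sites))) {
    anchor_idx <- if ("ligand" %in% names(sites) && !is.na(sites$ligand[i])) {
      if (is.numeric(sites$ligand)) {
        as.integer(sites$ligand[i])   # row index into `ligands`
      } else {
        hits <- which(ligands$name == sites$ligand[i])
        if (length(hits) == 0)
          stop("unknown anchor ligand '", sites$ligand[i], "'")
        hits[1]
      }
    } else 1L
    c_star <- centres[anchor_idx, ]

    if (all(c("dx", "dy", "dz") %in% names(sites)) &&
        !any(is.na(unlist(sites[i, c("dx", "dy", "dz")])))) {
      u <- as.numeric(sites[i, c("dx", "dy", "dz")])
    } else {
      # point away from the other ligand copies so distance grows monotonely
      away <- if (nrow(centres) > 1) {
        c_star - colMeans(centres[-anchor_idx, , drop = FALSE])
      } else c(0, 0, 0)
      u <- away + dirs[i, ] * max(1, sqrt(sum(away^2)))
    }
    u <- u / sqrt(sum(u^2))

    g <- function(t) min_dist_to_ligands(c_star + t * u) - sites$dist[i]
    lo <- 0.8
    hi <- sites$dist[i] + max(dist(rbind(centres, c_star))) + 5
    if (g(lo) > 0)
      stop("target distance ", sites$dist[i],
           " A too small given the ligand geometry (residue ",
           sites$chain[i], sites$resno[i], ")")
    t_star <- stats::uniroot(g, c(lo, hi), tol = 1e-9)$root
    xyz <- t(vapply(atom_offsets, function(off) c_star + (t_star + off) * u,
                    numeric(3)))
    achieved <- min(apply(xyz, 1, min_dist_to_ligands))
    if (abs(achieved - sites$dist[i]) > 0.01)
      stop("clashing placement: residue ", sites$chain[i], sites$resno[i],
           " achieved ", round(achieved, 3), " A vs target ", sites$dist[i])
    placed[[i]] <- xyz
  }

  lines <- character(0)
  serial <- 0L
  ord <- order(sites$chain, sites$resno)
  for (i in ord) {
    xyz <- placed[[i]]
    for (a in names(atom_offsets)) {
      serial <- serial + 1L
      lines <- c(lines, pdb_record("ATOM", serial, a,
                                   toupper(sites$resname[i]),
                                   sites$chain[i], sites$resno[i],
                                   xyz[a, ], atom_elems[[a]]))
    }
  }
  for (k in seq_len(nrow(ligands))) {
    for (j in 1:3) {
      serial <- serial + 1L
      lines <- c(lines, pdb_record("HETATM", serial, paste0("C", j),
                                   toupper(ligands$name[k]),
                                   ligands$chain[k], 900L + k,
                                   centres[k, ] + cluster_offsets[j, ], "C"))
    }
  }
  structure(c(lines, "END"), class = "toy_structure")
}

#' @export
print.toy_structure <- function(x, ...) {
  cat("Toy PDB structure,", sum(grepl("^ATOM", x)), "protein atoms,",
      sum(grepl("^HETATM", x)), "ligand atoms\n")
  invisible(x)
}

#' Parse a toy (or real) structure with bio3d
#'
#' Convenience wrapper accepting either a file path or in-memory PDB lines.
#' @param x file path, or a character vector of PDB lines
#'   (e.g. from [make_toy_structure()]).
#' @return a `bio3d` `pdb` object.
#' @export
read_structure <- function(x) {
  if (length(x) == 1 && file.exists(x)) return(bio3d::read.pdb(x))
  tmp <- tempfile(fileext = ".pdb")
  on.exit(unlink(tmp))
  writeLines(x, tmp)
  bio3d::read.pdb(tmp)
}
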