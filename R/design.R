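AA3_TO_1 <- c(ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C",
              GLN = "Q", GLU = "E", GLY = "G", HIS = "H", ILE = "I",
              LEU = "L", LYS = "K", MET = "M", PHE = "F", PRO = "P",
              SER = "S", THR = "T", TRP = "W", TYR = "Y", VAL = "V")

#' A designed mutant construct
#'
#' A named set of substitutions (and optional insertions) to introduce into
#' the thermophilic sequence, produced by the shell-selection, grouping and
#' insertion rules or constructed by hand.
#'
#' @param name construct label, e.g. `"mut#9"`.
#' @param substitutions data frame with columns `pos` (position in sequence
#'   A, unique), `from` (residue in A) and `to` (replacement residue from B).
#' @param insertions data frame with columns `after_pos` (position in A
#'   after which the insertion goes) and `residues` (inserted residue
#'   string), or NULL.
#' @param shell the selection radius (Angstrom) the sites came from, or NA.
#' @return object of class `mutant_design`.
#' @export
#' @examples
#' mutant_design("mut#9",
#'               data.frame(pos = c(272, 273), from = c("V", "H"),
#'                          to = c("A", "G")))
mutant_design <- function(name, substitutions,
                          insertions = NULL, shell = NA_real_) {
  stopifnot(all(c("pos", "from", "to") %in% names(substitutions)))
  if (anyDuplicated(substitutions$pos))
    stop("substitution positions must be unique")
  substitutions <- substitutions[order(substitutions$pos),
                                 c("pos", "from", "to")]
  rownames(substitutions) <- NULL
  if (is.null(insertions))
    insertions <- data.frame(after_pos = integer(0),
                             residues = character(0))
  structure(list(name = name, substitutions = substitutions,
                 insertions = insertions, shell = shell),
            class = "mutant_design")
}

#' Mutation strings of a design
#' @param design a [mutant_design()].
#' @return character vector in `"V272A"` notation.
#' @export
mutation_strings <- function(design) {
  s <- design$substitutions
  paste0(s$from, s$pos, s$to)
}

#' @export
print.mutant_design <- function(x, ...) {
  cat(sprintf("Mutant design %s: %s", x$name,
              paste(mutation_strings(x), collapse = " + ")))
  if (!is.na(x$shell)) cat(sprintf(" [shell %g A]", x$shell))
  cat("\n")
  if (nrow(x$insertions))
    cat("  insertions:",
        paste(sprintf("%s after %d", x$insertions$residues,
                      x$insertions$after_pos), collapse = "; "), "\n")
  invisible(x)
}

#' Select candidate substitution sites within a distance shell
#'
#' Implements the comparative shell rule: a position is a candidate when the
#' two aligned sequences differ there and the corresponding residue in the
#' structure lies within `radius` of any atom of any bound ligand. Distances
#' for a sequence position are minimised over chains, so dimer subunits
#' contribute symmetrically.
#'
#' @param aln an [alignment_map()]; sequence A is the structural/thermophile
#'   sequence.
#' @param dmap a [compute_distance_map()] result.
#' @param radius shell radius, Angstrom (8 and 12 in typical use).
#' @param offset integer added to positions in sequence A to obtain
#'   structure residue numbers.
#' @return data frame of class `shell_candidates` with columns `column`
#'   (alignment column), `pos_a`, `resno`, `from`, `to`, per-ligand
#'   distances and `min_dist`. Positions absent from the structure are
#'   skipped with a warning.
#' @export
select_shell_sites <- function(aln, dmap, radius, offset = 0L) {
  stopifnot(inherits(aln, "alignment_map"),
            inherits(dmap, "residue_distance_map"), radius > 0)
  lig_cols <- grep("^dist_", names(dmap), value = TRUE)
  # per sequence position: min over chains
  agg <- stats::aggregate(dmap[c(lig_cols, "min_dist")],
                          by = list(resno = dmap$resno), FUN = min)

  diff_cols <- which(aln$a != "-" & aln$b != "-" & aln$a != aln$b)
  out <- data.frame(column = integer(0), pos_a = integer(0),
                    resno = integer(0), from = character(0),
                    to = character(0), stringsAsFactors = FALSE)
  for (lc in lig_cols) out[[lc]] <- numeric(0)
  out$min_dist <- numeric(0)

  missing <- integer(0)
  for (j in diff_cols) {
    resno <- aln$pos_a[j] + offset
    k <- match(resno, agg$resno)
    if (is.na(k)) { missing <- c(missing, resno); next }
    if (agg$min_dist[k] <= radius) {
      row <- data.frame(column = j, pos_a = aln$pos_a[j], resno = resno,
                        from = aln$a[j], to = aln$b[j],
                        stringsAsFactors = FALSE)
      for (lc in lig_cols) row[[lc]] <- agg[[lc]][k]
      row$min_dist <- agg$min_dist[k]
      out <- rbind(out, row)
    }
  }
  if (length(missing))
    warning("skipped ", length(missing),
            " differing position(s) absent from the structure: ",
            paste(utils::head(missing, 10), collapse = ", "))
  rownames(out) <- NULL
  class(out) <- c("shell_candidates", "data.frame")
  attr(out, "radius") <- radius
  attr(out, "offset") <- offset
  out
}

#' Group candidate sites into mutant constructs
#'
#' Residues that are structurally close are replaced together in the same
#' construct: candidates are single-linkage clustered under the minimum
#' inter-residue heavy-atom distance, and each cluster becomes one
#' [mutant_design()]. Designs are numbered in order of their lowest residue
#' number.
#'
#' @param candidates a [select_shell_sites()] result.
#' @param pdb the structure the distances refer to (`bio3d` pdb or
#'   parseable input).
#' @param link_threshold linkage distance, Angstrom (default 6).
#' @param name_prefix prefix for construct names.
#' @return list of [mutant_design()] objects partitioning the candidates.
#' @export
group_sites <- function(candidates, pdb, link_threshold = 6,
                        name_prefix = "mut#") {
  stopifnot(inherits(candidates, "shell_candidates"))
  if (!inherits(pdb, "pdb")) pdb <- read_structure(pdb)
  n <- nrow(candidates)
  if (n == 0) return(list())

  # union-find over candidates linked when min heavy-atom distance <= cutoff
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  if (n > 1) {
    for (i in 1:(n - 1)) for (j in (i + 1):n) {
      d <- residue_pair_min_dist(pdb, candidates$resno[i],
                                 candidates$resno[j])
      if (!is.na(d) && d <= link_threshold) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[ri] <- rj
      }
    }
  }
  comp <- vapply(seq_len(n), find, integer(1))
  groups <- split(seq_len(n), comp)
  groups <- groups[order(vapply(groups, function(ix)
    min(candidates$resno[ix]), numeric(1)))]

  lapply(seq_along(groups), function(g) {
    ix <- groups[[g]]
    mutant_design(
      name = paste0(name_prefix, g),
      substitutions = data.frame(pos = candidates$pos_a[ix],
                                 from = candidates$from[ix],
                                 to = candidates$to[ix],
                                 stringsAsFactors = FALSE),
      shell = attr(candidates, "radius"))
  })
}

#' Attach insertions adjacent to substituted positions
#'
#' Residues inserted in sequence B are added to a design when the aligned
#' residue immediately flanking the insertion (on either side) is one of the
#' design's substitutions. An insertion flanked by substitutions belonging
#' to two different designs is attached to both, with a warning.
#'
#' @param designs list of [mutant_design()] referencing positions of
#'   sequence A.
#' @param aln the [alignment_map()] the designs came from.
#' @return the list of designs with `insertions` filled in.
#' @export
apply_insertion_rule <- function(designs, aln) {
  stopifnot(inherits(aln, "alignment_map"))
  gap_runs <- rle(aln$a == "-")
  ends <- cumsum(gap_runs$lengths)
  starts <- ends - gap_runs$lengths + 1
  runs <- which(gap_runs$values)
  for (r in runs) {
    cols <- starts[r]:ends[r]
    inserted <- paste(aln$b[cols], collapse = "")
    left_pos <- if (starts[r] > 1) aln$pos_a[starts[r] - 1] else NA
    right_pos <- if (ends[r] < nrow(aln)) aln$pos_a[ends[r] + 1] else NA
    flank <- stats::na.omit(c(left_pos, right_pos))
    hit <- vapply(designs, function(d) any(flank %in% d$substitutions$pos),
                  logical(1))
    if (sum(hit) > 1)
      warning("insertion '", inserted, "' is flanked by substitutions in ",
              sum(hit), " designs; attached to all of them")
    after <- if (!is.na(left_pos)) left_pos else 0L
    for (k in which(hit)) {
      designs[[k]]$insertions <- rbind(
        designs[[k]]$insertions,
        data.frame(after_pos = after, residues = inserted,
                   stringsAsFactors = FALSE))
    }
  }
  designs
}

#' Combine two mutant designs
#'
#' Union of substitutions and insertions, e.g. combining the best
#' single-construct mutations with other beneficial ones. Conflicting
#' substitutions (same position, different target residue) are an error.
#'
#' @param a,b [mutant_design()] objects.
#' @return a combined [mutant_design()] named in `"mut9/21"` style.
#' @export
#' @examples
#' m9 <- mutant_design("mut#9", data.frame(pos = c(272, 273),
#'                                         from = c("V", "H"),
#'                                         to = c("A", "G")))
#' m21 <- mutant_design("mut#21", data.frame(pos = 220, from = "A", to = "T"))
#' combine_designs(m9, m21)
combine_designs <- function(a, b) {
  stopifnot(inherits(a, "mutant_design"), inherits(b, "mutant_design"))
  subs <- rbind(a$substitutions, b$substitutions)
  subs <- unique(subs)
  dup <- subs$pos[duplicated(subs$pos)]
  if (length(dup))
    stop("conflicting substitutions at position(s) ",
         paste(unique(dup), collapse = ", "))
  ins <- unique(rbind(a$insertions, b$insertions))
  strip <- function(nm) sub("^mut#?", "", nm)
  nm <- paste0("mut", paste(unique(c(strip(a$name), strip(b$name))),
                            collapse = "/"))
  shell <- suppressWarnings(max(a$shell, b$shell, na.rm = TRUE))
  mutant_design(nm, subs, insertions = ins,
                shell = if (is.finite(shell)) shell else NA_real_)
}

#' Write shell candidates as TSV and designs as JSON
#'
#' @param candidates a [select_shell_sites()] result.
#' @param designs list of [mutant_design()].
#' @param candidates_path,designs_path output paths.
#' @return invisibly, the output paths.
#' @export
write_design_outputs <- function(candidates, designs,
                                 candidates_path, designs_path) {
  utils::write.table(as.data.frame(candidates), candidates_path,
                     sep = "\t", row.names = FALSE, quote = FALSE)
  jsonlite::write_json(
    lapply(designs, function(d)
      list(name = d$name,
           mutations = mutation_strings(d),
           substitutions = d$substitutions,
           insertions = d$insertions,
           shell = d$shell)),
    designs_path, auto_unbox = TRUE, digits = NA)
  invisible(c(candidates_path, designs_path))
}
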