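AA_STANDARD <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

#' Column-wise map of a pairwise protein alignment
#'
#' Stores an aligned sequence pair as one row per alignment column with the
#' residue (or `-`) and the 1-based ungapped position (or `NA`) in each
#' sequence.
#'
#' @param aligned_a,aligned_b aligned sequences of equal length, gaps as `-`.
#' @param names length-2 character, sequence labels.
#' @return data frame of class `alignment_map` with columns
#'   `a`, `b`, `pos_a`, `pos_b` and attribute `seq_names`.
#' @export
alignment_map <- function(aligned_a, aligned_b,
                          names = c("seqA", "seqB")) {
  a <- strsplit(toupper(aligned_a), "")[[1]]
  b <- strsplit(toupper(aligned_b), "")[[1]]
  if (length(a) != length(b))
    stop("aligned sequences must have equal length")
  if (any(a == "-" & b == "-"))
    stop("alignment has a column gapped in both sequences")
  pos_a <- ifelse(a == "-", NA_integer_, cumsum(a != "-"))
  pos_b <- ifelse(b == "-", NA_integer_, cumsum(b != "-"))
  out <- data.frame(a = a, b = b, pos_a = pos_a, pos_b = pos_b,
                    stringsAsFactors = FALSE)
  attr(out, "seq_names") <- names
  class(out) <- c("alignment_map", "data.frame")
  out
}

#' Global pairwise protein alignment
#'
#' Needleman-Wunsch global alignment (via `Biostrings::pairwiseAlignment`)
#' with affine gap penalties. Defaults follow common practice for protein
#' pairs: BLOSUM62, gap open 11, gap extend 1. If a reference alignment is
#' already available (e.g. from a publication's supplementary figure), build
#' the map directly with [alignment_map()] or [read_alignment_fasta()]
#' instead.
#'
#' @param seq_a,seq_b protein sequences (standard 20-letter alphabet).
#' @param matrix substitution matrix name available in Biostrings
#'   (e.g. "BLOSUM62").
#' @param gap_open,gap_extend positive gap penalties.
#' @param names sequence labels.
#' @return an [alignment_map()] with attribute `score`.
#' @export
#' @examples
#' align_global("ACDE", "ACE")
align_global <- function(seq_a, seq_b, matrix = "BLOSUM62",
                         gap_open = 11, gap_extend = 1,
                         names = c("seqA", "seqB")) {
  for (s in c(seq_a, seq_b)) {
    if (nchar(s) == 0) stop("sequences must be non-empty")
    bad <- setdiff(strsplit(toupper(s), "")[[1]], AA_STANDARD)
    if (length(bad))
      stop("non-standard amino acid character(s): ",
           paste(bad, collapse = ", "))
  }
  aln <- Biostrings::pairwiseAlignment(
    pattern = toupper(seq_a), subject = toupper(seq_b),
    type = "global", substitutionMatrix = matrix,
    gapOpening = gap_open, gapExtension = gap_extend)
  out <- alignment_map(as.character(Biostrings::alignedPattern(aln)),
                       as.character(Biostrings::alignedSubject(aln)),
                       names = names)
  attr(out, "score") <- Biostrings::score(aln)
  out
}

#' Read a two-record aligned FASTA into an alignment map
#'
#' @param path FASTA file with exactly two aligned (equal-length) records.
#' @return an [alignment_map()].
#' @export
read_alignment_fasta <- function(path) {
  seqs <- Biostrings::readAAStringSet(path)
  if (length(seqs) != 2)
    stop("aligned FASTA must contain exactly 2 records, found ",
         length(seqs))
  if (length(unique(Biostrings::width(seqs))) != 1)
    stop("aligned FASTA records have unequal lengths")
  alignment_map(as.character(seqs[[1]]), as.character(seqs[[2]]),
                names = names(seqs))
}

#' Summarise a pairwise alignment
#'
#' Counts identical and differing residue pairs over the columns where both
#' sequences have a residue, and the residues inserted in sequence B
#' (columns gapped in A) and deleted from B (columns gapped in B).
#'
#' @param aln an [alignment_map()].
#' @return list of class `alignment_summary` with `aligned_length` (columns
#'   ungapped in both), `identical`, `different`, `insertions_in_B`,
#'   `deletions_in_B`.
#' @export
summarize_alignment <- function(aln) {
  stopifnot(inherits(aln, "alignment_map"))
  both <- aln$a != "-" & aln$b != "-"
  structure(
    list(aligned_length = sum(both),
         identical = sum(both & aln$a == aln$b),
         different = sum(both & aln$a != aln$b),
         insertions_in_B = sum(aln$a == "-"),
         deletions_in_B = sum(aln$b == "-")),
    class = "alignment_summary")
}

#' @export
print.alignment_summary <- function(x, ...) {
  cat(sprintf(
    "Pairwise alignment: %d aligned residue pairs (%d identical, %d different)\n",
    x$aligned_length, x$identical, x$different))
  cat(sprintf("  %d residue(s) inserted in B, %d deleted from B\n",
              x$insertions_in_B, x$deletions_in_B))
  invisible(x)
}
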