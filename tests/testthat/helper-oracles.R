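# Independent oracles used to cross-check the package's computations.

# Closed-form ordinary least squares (sum formulas, no lm()).
ols_oracle <- function(x, y) {
  sx <- sum((x - mean(x)) * (y - mean(y)))
  slope <- sx / sum((x - mean(x))^2)
  list(slope = slope, intercept = mean(y) - slope * mean(x))
}

# Sum-formula Pearson correlation.
pearson_oracle <- function(x, y) {
  n <- length(x)
  (sum(x * y) - n * mean(x) * mean(y)) /
    sqrt((sum(x^2) - n * mean(x)^2) * (sum(y^2) - n * mean(y)^2))
}

# Brute-force minimum heavy-atom distance from one residue to one ligand:
# plain double loop over atom pairs.
brute_res_lig_dist <- function(pdb, chain, resno, lig) {
  at <- pdb$atom
  heavy <- is.na(at$elesy) | toupper(trimws(at$elesy)) != "H"
  ra <- at[at$type == "ATOM" & at$chain == chain & at$resno == resno &
             heavy, c("x", "y", "z")]
  la <- at[at$type == "HETATM" & at$resid == lig & heavy,
           c("x", "y", "z")]
  best <- Inf
  for (i in seq_len(nrow(ra))) for (j in seq_len(nrow(la)))
    best <- min(best, sqrt(sum((as.numeric(ra[i, ]) -
                                  as.numeric(la[j, ]))^2)))
  best
}

# Brute-force minimum heavy-atom distance between two residues (any chain).
brute_res_pair_dist <- function(pdb, resno_a, resno_b) {
  at <- pdb$atom
  heavy <- is.na(at$elesy) | toupper(trimws(at$elesy)) != "H"
  ra <- at[at$type == "ATOM" & at$resno == resno_a & heavy,
           c("x", "y", "z")]
  rb <- at[at$type == "ATOM" & at$resno == resno_b & heavy,
           c("x", "y", "z")]
  best <- Inf
  for (i in seq_len(nrow(ra))) for (j in seq_len(nrow(rb)))
    best <- min(best, sqrt(sum((as.numeric(ra[i, ]) -
                                  as.numeric(rb[j, ]))^2)))
  best
}

# Exhaustive global-alignment optimum for tiny sequences under affine gap
# scoring (gap run of length L costs open + L * ext). Recursion over all
# monotone alignments; exponential, fine for length <= 5.
enum_align_score <- function(a, b, open = 11, ext = 1) {
  sm <- NULL
  utils::data("BLOSUM62", package = "Biostrings", envir = environment())
  sm <- get("BLOSUM62", envir = environment())
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  rec <- function(i, j, prev) {
    if (i > length(av) && j > length(bv)) return(0)
    best <- -Inf
    if (i <= length(av) && j <= length(bv))
      best <- max(best, sm[av[i], bv[j]] + rec(i + 1, j + 1, "M"))
    if (j <= length(bv))  # gap in A, consumes b[j]
      best <- max(best, -(if (identical(prev, "A")) ext else open + ext) +
                    rec(i, j + 1, "A"))
    if (i <= length(av))  # gap in B, consumes a[i]
      best <- max(best, -(if (identical(prev, "B")) ext else open + ext) +
                    rec(i + 1, j, "B"))
    best
  }
  rec(1, 1, "M")
}

# Random toy structure plus the matching all-different alignment, for
# property tests of the shell / grouping rules.
random_design_fixture <- function(seed, n_min = 4, n_max = 8) {
  set.seed(seed)
  n <- sample(n_min:n_max, 1)
  sites <- data.frame(chain = "A", resno = seq_len(n),
                      resname = sample(c("ALA", "VAL", "SER", "HIS"), n,
                                       replace = TRUE),
                      dist = round(runif(n, 2.5, 14), 2))
  pdb <- read_structure(make_toy_structure(sites))
  from <- sample(c("A", "V", "L"), n, replace = TRUE)
  to <- vapply(from, function(f) sample(setdiff(c("G", "S", "T"), f), 1), "")
  keep_same <- runif(n) < 0.3
  to[keep_same] <- from[keep_same]
  aln <- alignment_map(paste(from, collapse = ""), paste(to, collapse = ""))
  list(sites = sites, pdb = pdb, aln = aln)
}

# Shared tolerance for "recovered to >= 6 significant digits".
rel_err <- function(est, truth) abs(est - truth) / abs(truth)
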