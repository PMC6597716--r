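test_that("global alignment matches an exhaustive tiny-sequence oracle", {
  id <- align_global("ACDE", "ACDE")
  s <- summarize_alignment(id)
  expect_equal(s$identical, 4)
  expect_equal(s$different, 0)
  expect_equal(s$insertions_in_B + s$deletions_in_B, 0)

  for (pair in list(c("ACDE", "ACE"), c("ACDE", "ACDE"),
                    c("WKDE", "WDE"), c("AC", "KACD"))) {
    aln <- align_global(pair[1], pair[2])
    expect_equal(attr(aln, "score"),
                 enum_align_score(pair[1], pair[2]),
                 info = paste(pair, collapse = "/"))
  }

  gap <- align_global("ACDE", "ACE")
  expect_equal(sum(gap$b == "-"), 1)
  expect_equal(sum(gap$a == "-"), 0)

  expect_error(align_global("AC1E", "ACE"), "non-standard")
  expect_error(align_global("", "ACE"), "non-empty")
})

test_that("alignment summaries count identities, differences and insertions", {
  m <- alignment_map("ACDE", "AGDE")
  s <- summarize_alignment(m)
  expect_equal(s$identical, 3)
  expect_equal(s$different, 1)

  # invariant: identical + different = columns ungapped in both
  m2 <- alignment_map("AC-DEF-G", "ACWDE-KG")
  s2 <- summarize_alignment(m2)
  both <- sum(m2$a != "-" & m2$b != "-")
  expect_equal(s2$identical + s2$different, both)
  expect_equal(s2$insertions_in_B, 2)
  expect_equal(s2$deletions_in_B, 1)

  expect_error(alignment_map("A-C", "A-C"), "gapped in both")
})

test_that("distance maps take the minimum over ligand copies and chains", {
  # residue anchored 3 A from the IPM copy at (40,0,0); the copy at origin
  # is ~20x further away and must not mask the minimum
  ligs <- data.frame(name = c("IPM", "IPM"), chain = c("A", "B"),
                     x = c(0, 40), y = 0, z = 0)
  sites <- data.frame(chain = "A", resno = 7, resname = "ALA",
                      dist = 3, ligand = 2)
  pdb <- read_structure(make_toy_structure(sites, ligands = ligs))
  dm <- compute_distance_map(pdb, ligands = "IPM")
  expect_equal(dm$dist_IPM, 3, tolerance = 0.011)
  expect_equal(dm$dist_IPM, brute_res_lig_dist(pdb, "A", 7, "IPM"),
               tolerance = 1e-9)

  # an overlap-range distance is reported as-is, no clamping
  near <- read_structure(make_toy_structure(
    data.frame(chain = "A", resno = 1, resname = "ALA", dist = 1.2)))
  expect_equal(compute_distance_map(near)$min_dist, 1.2, tolerance = 0.011)

  expect_error(compute_distance_map(pdb, ligands = "NAD"),
               "available HET groups")
})

test_that("shell selection keeps differing residues within the radius", {
  sites <- data.frame(chain = "A", resno = 1:4, resname = "ALA",
                      dist = c(5, 10, 13, 4))
  pdb <- read_structure(make_toy_structure(sites))
  dm <- compute_distance_map(pdb)

  aln_same <- alignment_map("AAAA", "AAAA")
  expect_equal(nrow(select_shell_sites(aln_same, dm, 12)), 0)

  aln <- alignment_map("AAAA", "GGGA")  # site 4 identical
  c8 <- select_shell_sites(aln, dm, 8)
  c12 <- select_shell_sites(aln, dm, 12)
  expect_equal(c8$resno, 1)             # 10 A site excluded at 8 A
  expect_equal(c12$resno, c(1, 2))      # included at 12 A, 13 A still out
  expect_true(all(c8$resno %in% c12$resno))
  expect_false(4 %in% c12$resno)        # identical column never a candidate

  # a differing position missing from the structure is skipped with warning
  aln5 <- alignment_map("AAAAA", "GGGAG")
  expect_warning(c5 <- select_shell_sites(aln5, dm, 12), "absent")
  expect_equal(c5$resno, c(1, 2))
})

test_that("grouping is single-linkage and partitions the candidates", {
  # three residues along one ray: adjacent gaps pass the threshold, the
  # ends only connect through the middle (single linkage)
  sites <- data.frame(chain = "A", resno = 1:3, resname = "ALA",
                      dist = c(5, 10.5, 16),
                      dx = 1, dy = 0, dz = 0)
  pdb <- read_structure(make_toy_structure(sites))
  dm <- compute_distance_map(pdb)
  aln <- alignment_map("AAA", "GGG")
  cand <- select_shell_sites(aln, dm, 20)
  expect_gt(brute_res_pair_dist(pdb, 1, 3), 6)
  one <- group_sites(cand, pdb, link_threshold = 6)
  expect_length(one, 1)
  expect_equal(one[[1]]$substitutions$pos, 1:3)

  # far-apart residues give singleton designs, ordered by residue number
  sites2 <- data.frame(chain = "A", resno = c(2, 9), resname = "ALA",
                       dist = c(8, 8), dx = c(1, -1), dy = 0, dz = 0)
  pdb2 <- read_structure(make_toy_structure(sites2))
  cand2 <- select_shell_sites(alignment_map("AAAAAAAAA", "AGAAAAAAG"),
                              compute_distance_map(pdb2), 20)
  two <- group_sites(cand2, pdb2, link_threshold = 6)
  expect_length(two, 2)
  expect_equal(vapply(two, function(d) d$substitutions$pos, numeric(1)),
               c(2, 9))

  # partition: every candidate in exactly one design
  pos <- sort(unlist(lapply(one, function(d) d$substitutions$pos)))
  expect_equal(pos, sort(cand$pos_a))
})

test_that("insertions attach to designs with an adjacent substitution", {
  aln <- alignment_map("AC-DE", "AGWDE")  # C->G substitution flanks the W
  d <- list(mutant_design("mut#1",
                          data.frame(pos = 2, from = "C", to = "G")))
  out <- apply_insertion_rule(d, aln)
  expect_equal(out[[1]]$insertions$residues, "W")
  expect_equal(out[[1]]$insertions$after_pos, 2)

  # no flanking substitution anywhere: never attached
  d2 <- list(mutant_design("mut#1",
                           data.frame(pos = 4, from = "E", to = "K")))
  out2 <- apply_insertion_rule(d2, aln)
  expect_equal(nrow(out2[[1]]$insertions), 0)

  # flanked by substitutions in two different designs: attached to both
  aln3 <- alignment_map("AC-DE", "AGWSE")
  d3 <- list(mutant_design("mut#1", data.frame(pos = 2, from = "C", to = "G")),
             mutant_design("mut#2", data.frame(pos = 3, from = "D", to = "S")))
  expect_warning(out3 <- apply_insertion_rule(d3, aln3), "2 designs")
  expect_equal(out3[[1]]$insertions$residues, "W")
  expect_equal(out3[[2]]$insertions$residues, "W")
})

test_that("combining designs unions substitutions and rejects conflicts", {
  known <- ipmdh_known_mutations()
  best <- combine_designs(known[["mut#9"]], known[["mut#21"]])
  expect_equal(best$name, "mut9/21")
  expect_equal(nrow(best$substitutions), 3)
  expect_setequal(mutation_strings(best), c("A220T", "V272A", "H273G"))

  expect_identical(combine_designs(known[["mut#9"]], known[["mut#9"]])
                   $substitutions,
                   known[["mut#9"]]$substitutions)

  a <- mutant_design("x", data.frame(pos = 10, from = "A", to = "G"))
  b <- mutant_design("y", data.frame(pos = 10, from = "A", to = "S"))
  expect_error(combine_designs(a, b), "conflict")
})
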