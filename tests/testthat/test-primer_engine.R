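# primer_engine: consensus, degeneracy, expansions, NN thermodynamics,
# pair design and panel validation

test_that("iupac_consensus maps base sets to the unique covering code", {
  expect_equal(iupac_consensus(list("A", c("A", "G"), c("C", "G", "T"))),
               "ARB")
  expect_equal(iupac_consensus(list("G", "A", "T")), "GAT")
  expect_equal(iupac_consensus(list(c("A", "C", "G", "T"))), "N")
  expect_error(iupac_consensus(list(character(0))), "empty")
  expect_error(iupac_consensus(list(c("A", "-"))), "gap")
})

test_that("degeneracy is the product of expansion-set sizes", {
  expect_equal(degeneracy("ACGT"), 1)
  expect_equal(degeneracy("RYN"), 16)
  expect_error(degeneracy(""), "empty")
  # oracle: count of enumerate_expansions output
  set.seed(31)
  codes <- names(panelforge:::IUPAC_BITS)
  for (rep in 1:10) {
    s <- paste(sample(codes, 6, replace = TRUE), collapse = "")
    expect_equal(degeneracy(s), length(enumerate_expansions(s, cap = 5000L)))
  }
})

test_that("enumerate_expansions is lexicographic, capped and seeded", {
  expect_equal(enumerate_expansions("AR"), c("AA", "AG"))
  expect_equal(enumerate_expansions("N", cap = 4L), c("A", "C", "G", "T"))
  s <- strrep("N", 5)                       # degeneracy 1024
  e1 <- enumerate_expansions(s, cap = 64L, seed = 9L)
  e2 <- enumerate_expansions(s, cap = 64L, seed = 9L)
  expect_identical(e1, e2)
  expect_equal(length(e1), 64L)
  expect_equal(anyDuplicated(e1), 0L)
  expect_true(all(c("AAAAA", "TTTTT") %in% e1))  # lexicographic extremes
  e3 <- enumerate_expansions(s, cap = 64L, seed = 10L)
  expect_false(identical(e1, e3))
})

# frozen from an independent nearest-neighbor implementation (Biopython
# MeltingTemp.Tm_NN, unified table DNA_NN3, Na=50 mM, Mg=1.5 mM,
# dnac1=dnac2=250 nM, entropic salt correction) — agreement within 0.5 C
BIOPYTHON_TM <- c(
  AGCGTACGTTAGCCAGGTCA = 65.4827,
  ATATATATATATATATATAT = 33.9753,
  GCGCGCGCGCGCGCGCGCGC = 86.3967,
  ACGTTGCAAGTCCTGAATCG = 62.9822,
  TTGACCTGGCTAACGTACGC = 64.5420,
  CCTGAAGGGATCACCAGTAA = 60.5218,
  AGTCAGTCAGTCAGTCAG   = 57.2512,
  GGGATCCTCTAGAGTCGACCTGCAGGCA = 73.6973)

test_that("tm_nn matches the independent NN oracle within 0.5 C", {
  for (s in names(BIOPYTHON_TM)) {
    expect_lt(abs(tm_nn(s) - BIOPYTHON_TM[[s]]), 0.5)
  }
})

test_that("tm_nn obeys GC and length monotonicity", {
  expect_gt(tm_nn("GCGCGCGCGCGCGCGCGCGC"), tm_nn("ATATATATATATATATATAT"))
  s24 <- "GACTGCAGCTGGATCCGAGCTCGA"
  expect_gte(tm_nn(s24), tm_nn(substr(s24, 1, 18)))
  expect_error(tm_nn("ACGT"), ">= 6")
  expect_error(tm_nn("ACGTNACGTA"), "ambiguity")
})

test_that("tm_range_degenerate brackets expansion Tms exactly under the cap", {
  expect_equal(unname(diff(tm_range_degenerate("ACGTACGTACGTACGTAC"))), 0)
  r <- tm_range_degenerate("ACGTACGTACRTACGTAC", cap = 4L)
  tma <- tm_nn("ACGTACGTACATACGTAC"); tmg <- tm_nn("ACGTACGTACGTACGTAC")
  expect_equal(unname(r), c(min(tma, tmg), max(tma, tmg)))
  set.seed(13)
  for (rep in 1:5) {
    base <- strsplit(random_dna(18), "")[[1]]
    pos <- sample(18, 3)
    base[pos] <- sample(c("R", "Y", "S", "W", "K", "M"), 3, replace = TRUE)
    s <- paste(base, collapse = "")              # degeneracy 8 <= 64
    ex <- enumerate_expansions(s, cap = 64L)
    tms <- vapply(ex, tm_nn, numeric(1))
    r2 <- tm_range_degenerate(s, cap = 64L)
    expect_equal(unname(r2), c(min(tms), max(tms)))
    expect_true(all(tms >= r2[["tm_min"]] & tms <= r2[["tm_max"]]))
  }
})

test_that("hairpin_tm finds designed stems and returns -Inf when none", {
  expect_identical(hairpin_tm("AAAAAAAAAAAA"), -Inf)
  with_stem <- "GGGGCAAAAAAGCCCC"       # 4-bp stem, 7-nt loop
  expect_true(is.finite(hairpin_tm(with_stem)))
  expect_identical(hairpin_tm("GGGGCAAAAAA"), -Inf)  # 3' arm removed
  expect_error(hairpin_tm("ACGTAACGTN"), "ambiguity")
})

test_that("hairpin_tm equals the brute-force stem oracle for length <= 20", {
  set.seed(17)
  for (rep in 1:25) {
    s <- random_dna(sample(10:20, 1))
    expect_equal(hairpin_tm(s), oracle_hairpin(s), tolerance = 1e-9)
  }
})

test_that("duplex_dg: perfect duplex, no-complement zero, offset oracle", {
  s <- "ACGGTCCAGTTCAA"
  expect_equal(duplex_dg(s, reverse_complement(s)), full_duplex_dg(s),
               tolerance = 1e-9)
  expect_equal(duplex_dg("AAAA", "AAAA"), 0)
  set.seed(23)
  for (rep in 1:25) {
    a <- random_dna(sample(8:16, 1)); b <- random_dna(sample(8:16, 1))
    expect_equal(duplex_dg(a, b), oracle_duplex(a, b), tolerance = 1e-9)
  }
})

test_that("design_pair returns a perfect pair on a conserved alignment", {
  set.seed(3)
  base <- random_dna(600)
  aln <- as_alignment(seq_set(paste0("m", 1:4), rep(base, 4),
                              alphabet = "dna", gapped = TRUE))
  ps <- design_pair(aln, group_id = "g")
  expect_gt(length(ps), 0L)
  top <- ps[[1]]
  expect_equal(top$forward$degeneracy, 1)
  expect_equal(top$reverse$degeneracy, 1)
  expect_equal(top$expected_len, top$rev_end - top$fwd_start)
  # both primers match every member exactly (consensus correctness)
  for (sq in aln$seq) {
    expect_equal(nrow(find_binding_sites(top$forward$iupac_seq, sq,
                                         max_mm = 0L)), 1L)
    expect_equal(nrow(find_binding_sites(top$reverse$iupac_seq, sq,
                                         max_mm = 0L)), 1L)
  }
  # every emitted pair satisfies the three constraints
  for (pp in ps) {
    for (pr in list(pp$forward, pp$reverse)) {
      expect_gte(pr$tm_min, 40); expect_lte(pr$tm_max, 65)
      expect_lte(pr$hairpin_tm, 25)
      expect_lte(abs(pr$dg_worst_dimer),
                 (1 / 3) * min(abs(pp$forward$dg_full_duplex),
                               abs(pp$reverse$dg_full_duplex)) + 1e-9)
    }
  }
})

test_that("design_pair reports diagnostics when constraints bind", {
  # alignment whose non-gap windows are all maximally degenerate: every
  # column differs across the 4 members
  set.seed(8)
  rows <- vapply(1:4, function(i) {
    paste(c("A", "C", "G", "T")[(seq_len(400) + i) %% 4 + 1], collapse = "")
  }, character(1))
  aln <- as_alignment(seq_set(paste0("m", 1:4), rows, alphabet = "dna",
                              gapped = TRUE))
  ps <- design_pair(aln, design_constraints(degeneracy_cap = 64))
  expect_length(ps, 0L)
  dg <- attr(ps, "diagnostics")
  expect_gt(dg[["degeneracy"]], 0L)
  expect_equal(sum(dg[c("tm", "hairpin", "dimer")]), 0L)
  expect_error(design_pair(aln[1]), ">= 2 rows")
})

test_that("design + in-silico screen recovers 100% of group members", {
  fam <- make_two_group_family(seed = 77)
  groups <- partition_tree(fam$tree, patristic_distances(fam$tree),
                           max_within = 2)
  res <- design_panel(fam$alignment, groups, seed = 1L)
  expect_equal(sort(res$panel$group_id), c("1", "2"))
  v <- validate_panel(res$panel, fam$sequences, fam$membership)
  expect_equal(v$coverage, c(1, 1))
  expect_length(attr(v, "missed"), 0L)
})

test_that("validate_panel flags 3'-end mutations and bad inputs", {
  fam <- make_two_group_family(seed = 78)
  groups <- partition_tree(fam$tree, patristic_distances(fam$tree),
                           max_within = 2)
  res <- design_panel(fam$alignment, groups, seed = 1L)
  pair <- res$pairs[["1"]]
  seqs <- fam$sequences
  # mutate the forward primer's 3'-terminal base inside member 1
  target <- seqs$seq[1]
  site <- find_binding_sites(pair$forward$iupac_seq, target, max_mm = 0L)
  site <- site[site$strand == "+", ][1, ]
  pos <- site$end               # 0-based half-open: last primer base
  ch <- substr(target, pos, pos)
  sub <- setdiff(c("A", "C", "G", "T"), ch)[1]
  mutated <- paste0(substr(target, 1, pos - 1), sub,
                    substr(target, pos + 1, nchar(target)))
  seqs$seq[1] <- mutated
  v <- validate_panel(res$panel, seqs, fam$membership)
  expect_true(seqs$id[1] %in% attr(v, "missed"))
  expect_lt(v$coverage[v$group_id == "1"], 1)

  expect_error(validate_panel(res$panel, seqs[integer(0)], fam$membership),
               "empty design set")
  badm <- fam$membership; badm[1] <- "99"
  expect_error(validate_panel(res$panel, fam$sequences, badm), "absent")
})
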