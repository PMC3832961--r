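# amplicon_pipeline: trimming, length gates, translation, identity,
# classification, chimera screen, clustering, novelty, distribution

test_that("trim_and_filter performs the 4/21 trim and drops bad reads", {
  set.seed(101)
  good <- random_dna(102)
  reads <- seq_set(c("r1", "r2", "r3"),
                   c(good, strrep("A", 102), paste0(random_dna(40))),
                   alphabet = "dna")
  spec <- trim_spec(head_trim = 4L, tail_trim = 21L, min_len = 77L)
  out <- trim_and_filter(reads, spec)
  expect_equal(out$id, "r1")
  expect_equal(nchar(out$seq), 77L)
  expect_equal(out$seq, substr(good, 5, 81))
  log <- attr(out, "log")
  expect_equal(log[["low_complexity"]], 1L)   # poly-A read
  expect_equal(log[["too_short"]], 1L)
  expect_equal(log[["kept"]], 1L)
})

test_that("adapter-containing reads are dropped, clean twins retained", {
  set.seed(102)
  adapter <- "AGATCGGAAGAGCACACGTC"
  clean <- random_dna(102)
  with_ad <- paste0(substr(clean, 1, 40), adapter,
                    substr(clean, 61, 102))
  reads <- seq_set(c("clean", "dirty"), c(clean, with_ad), alphabet = "dna")
  spec <- trim_spec(head_trim = 4L, tail_trim = 21L, min_len = 77L,
                    adapter_seqs = adapter)
  out <- trim_and_filter(reads, spec)
  expect_equal(out$id, "clean")
  expect_equal(attr(out, "log")[["adapter"]], 1L)
  # a read that IS the adapter (padded to length) is dropped too
  rd <- seq_set("ad", paste0(adapter, random_dna(82)), alphabet = "dna")
  expect_equal(length(trim_and_filter(rd, spec)), 0L)
})

test_that("trim_and_filter errors when nothing can survive", {
  reads <- seq_set("r", random_dna(20), alphabet = "dna")
  expect_error(trim_and_filter(reads, trim_spec(head_trim = 15L,
                                                tail_trim = 10L)),
               "no reads survive")
})

test_that("length_gates applies strict >250 / >500 cut-offs", {
  contigs <- seq_set(paste0("c", 1:4),
                     vapply(c(250, 251, 500, 501), random_dna, character(1)),
                     alphabet = "dna")
  g <- length_gates(contigs)
  expect_setequal(g$reporting$id, c("c2", "c3", "c4"))
  expect_setequal(g$external$id, "c4")
  empty <- contigs[integer(0)]
  g0 <- length_gates(empty)
  expect_equal(length(g0$reporting), 0L)
  expect_equal(length(g0$external), 0L)
  big <- seq_set(paste0("b", 1:3), vapply(rep(1000, 3), random_dna,
                                          character(1)), alphabet = "dna")
  gb <- length_gates(big)
  expect_equal(length(gb$reporting), 3L)
  expect_equal(length(gb$external), 3L)
})

test_that("translate_longest_orf is frame-aware and strand-symmetric", {
  set.seed(103)
  # build an uninterrupted frame +1 ORF: 80 non-stop codons
  codons <- names(Biostrings::GENETIC_CODE)
  sense <- codons[Biostrings::GENETIC_CODE != "*"]
  orf <- paste(sample(sense, 80, replace = TRUE), collapse = "")
  got <- translate_longest_orf(orf)
  expect_equal(got$frame, 1L)
  expect_equal(nchar(got$protein), 80L)
  expect_equal(got$nt_start, 0L)
  expect_equal(got$nt_end, 240L)

  rc <- reverse_complement(orf)
  got2 <- translate_longest_orf(rc)
  expect_equal(got2$protein, got$protein)
  expect_equal(got2$frame, -1L)

  # 60-nt contig cannot hold a 30-codon ORF in any frame
  expect_null(translate_longest_orf(random_dna(60), min_codons = 30L))
})

test_that("translate_longest_orf equals the 6-frame brute-force oracle", {
  set.seed(104)
  for (rep in 1:20) {
    s <- random_dna(sample(120:600, 1))
    got <- translate_longest_orf(s, min_codons = 5L)
    want <- oracle_longest_orf(s, min_codons = 5L)
    if (is.null(want)) {
      expect_null(got)
    } else {
      expect_equal(got$protein, want)
    }
  }
})

test_that("compute_pid returns identity and coverage as specified", {
  p <- random_protein(100)
  r <- compute_pid(p, p)
  expect_equal(r$pid, 100)
  expect_equal(r$query_coverage, 1)

  q <- p
  substr(q, 50, 50) <- if (substr(q, 50, 50) == "A") "V" else "A"
  r2 <- compute_pid(q, p)
  expect_equal(r2$pid, 99)
  expect_equal(r2$query_coverage, 1)
  expect_error(compute_pid("", p), "empty")
})

test_that("compute_pid is symmetric on gap-free equal-length pairs", {
  # equal-length mutated copies align gap-free, so the identity fraction
  # must not depend on argument order
  set.seed(105)
  aas <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  for (rep in 1:8) {
    a <- random_protein(60)
    ch <- strsplit(a, "")[[1]]
    pos <- sample(60, sample(1:12, 1))
    ch[pos] <- vapply(ch[pos], function(x) sample(setdiff(aas, x), 1),
                      character(1))
    b <- paste(ch, collapse = "")
    expect_equal(compute_pid(a, b)$pid, compute_pid(b, a)$pid)
    expect_equal(compute_pid(a, b)$query_coverage, 1)
  }
})

test_that("classify assigns best hits, gates and non-specific labels", {
  set.seed(106)
  refA <- random_protein(220); refB <- random_protein(220)
  refs <- seq_set(c("refA", "refB"), c(refA, refB), alphabet = "protein")
  groups <- c(refA = "3", refB = "8")
  # query identical to refA; a 201-aa and a 200-aa truncation; a decoy
  # decoy: low-complexity repeat, far below the 25% identity gate
  queries <- seq_set(
    c("hitA", "len201", "len200", "decoy"),
    c(refA, substr(refB, 1, 201), substr(refB, 1, 200), strrep("PG", 105)),
    alphabet = "protein")
  hits <- classify(queries, refs, groups)
  h <- hits[hits$query_id == "hitA", ]
  expect_equal(h$best_ref_id, "refA")
  expect_equal(h$group_id, "3")
  expect_equal(h$pid, 100)
  expect_true(h$passed_length_gate)
  expect_true(hits$passed_length_gate[hits$query_id == "len201"])
  expect_false(hits$passed_length_gate[hits$query_id == "len200"])
  # reversed-sequence decoy: low identity -> non-specific
  expect_equal(hits$group_id[hits$query_id == "decoy"], "non-specific")
  expect_error(classify(queries, refs[integer(0)], groups), "empty reference")
})

test_that("classification is invariant to reference order", {
  set.seed(107)
  refs <- seq_set(paste0("r", 1:5),
                  vapply(rep(150, 5), random_protein, character(1)),
                  alphabet = "protein")
  groups <- stats::setNames(as.character(1:5), refs$id)
  q <- refs$seq[3]
  substr(q, 10, 10) <- "A"
  queries <- seq_set("q", q, alphabet = "protein")
  h1 <- classify(queries, refs, groups)
  perm <- refs[c(4, 2, 5, 1, 3)]
  h2 <- classify(queries, perm, groups)
  expect_equal(h1$best_ref_id, h2$best_ref_id)
  expect_equal(h1$group_id, h2$group_id)
})

test_that("chimera_screen flags cross-group splices only", {
  fam <- make_two_group_family(seed = 109)
  refs <- fam$sequences
  groups <- fam$membership
  g1 <- refs$seq[1]                       # group 1 member
  g2 <- refs$seq[8]                       # group 2 member
  splice <- paste0(substr(g1, 1, 450), substr(g2, 451, 900))
  v <- chimera_screen(splice, refs, groups)
  expect_equal(v$verdict, "chimeric")
  expect_setequal(v$half_groups, c("1", "2"))

  intact <- chimera_screen(g1, refs, groups)
  expect_equal(intact$verdict, "clean")
  expect_equal(unique(intact$half_groups), "1")

  expect_equal(chimera_screen(random_dna(399), refs, groups)$verdict,
               "untestable")
  # one half unrelated to any reference: insufficient evidence, not flagged
  set.seed(9)
  half_novel <- paste0(substr(g1, 1, 450), random_dna(450))
  expect_equal(chimera_screen(half_novel, refs, groups)$verdict, "clean")
})

test_that("cluster_types groups by >=90% identity with verified types", {
  set.seed(110)
  proto <- random_protein(210)
  mutate <- function(s, k) {
    ch <- strsplit(s, "")[[1]]
    pos <- sample(length(ch), k)
    ch[pos] <- vapply(ch[pos], function(x)
      sample(setdiff(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], x), 1),
      character(1))
    paste(ch, collapse = "")
  }
  a <- proto; b <- mutate(proto, 10)          # ~95% to proto
  c_ <- random_protein(210)                   # unrelated
  prot <- seq_set(c("A", "B", "C"), c(a, b, c_), alphabet = "protein")
  labels <- c(A = "s1", B = "s2", C = "s1")
  types <- cluster_types(prot, labels)
  expect_length(types, 2L)

  same <- seq_set(paste0("x", 1:4), rep(proto, 4), alphabet = "protein")
  types2 <- cluster_types(same, stats::setNames(rep("s1", 4), same$id))
  expect_length(types2, 1L)
  expect_equal(nrow(types2[[1]]$members), 4L)

  expect_error(cluster_types(prot, labels, threshold = 0), "0,100")
})

test_that("cluster_types matches the brute-force clique-cover oracle", {
  set.seed(111)
  aas <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  for (rep in 1:15) {
    nproto <- sample(1:3, 1)
    protos <- vapply(rep(200, nproto), random_protein, character(1))
    n <- sample(3:6, 1)
    seqs <- vapply(seq_len(n), function(i) {
      p <- protos[sample(nproto, 1)]
      ch <- strsplit(p, "")[[1]]
      k <- sample(0:8, 1)
      if (k > 0) {
        pos <- sample(length(ch), k)
        ch[pos] <- vapply(ch[pos], function(x) sample(setdiff(aas, x), 1),
                          character(1))
      }
      paste(ch, collapse = "")
    }, character(1))
    prot <- seq_set(sprintf("q%02d", seq_len(n)), seqs, alphabet = "protein")
    labels <- stats::setNames(rep("s", n), prot$id)
    types <- cluster_types(prot, labels)
    # soundness: all pairs within a type >= 90
    pid_of <- function(x, y) compute_pid(x, y, "protein")$pid
    for (tp in types) {
      mem <- tp$members$id
      if (length(mem) > 1) {
        for (i in 1:(length(mem) - 1)) for (j in (i + 1):length(mem)) {
          expect_gte(pid_of(prot$seq[match(mem[i], prot$id)],
                            prot$seq[match(mem[j], prot$id)]), 90)
        }
      }
    }
    # optimality on these near-transitive sets
    pids <- matrix(100, n, n)
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (i != j) pids[i, j] <- pid_of(seqs[i], seqs[j])
    }
    pids <- pmin(pids, t(pids))
    expect_equal(length(types), oracle_min_clique_cover(pids, 90))
  }
})

test_that("novelty_bins uses the published bin edges", {
  nb <- novelty_bins(c(100, 95, 50))
  expect_equal(unname(nb$counts), c(1L, 1L, 1L, 0L))
  nb2 <- novelty_bins(c(90, 89.999, 100, 29.9))
  expect_equal(nb2$counts[["high_90_99"]], 1L)
  expect_equal(nb2$counts[["novel_30_89"]], 1L)
  expect_equal(nb2$counts[["identical"]], 1L)
  expect_equal(nb2$counts[["unassigned"]], 1L)
  expect_equal(sum(nb2$counts), 4L)           # bins partition the input
  nb0 <- novelty_bins(numeric(0))
  expect_true(all(nb0$counts == 0L))
  expect_error(novelty_bins(c(50, 101)), "outside")
})

test_that("distribution_matrix orders rows and flags unique types", {
  mk_type <- function(id, labels) {
    structure(list(type_id = id, centroid_id = paste0(id, "_c"),
                   members = data.frame(id = paste0(id, seq_along(labels)),
                                        label = labels,
                                        stringsAsFactors = FALSE)),
              class = "rdha_type")
  }
  study <- paste0("s", 1:6)
  refs <- c("genomeA", "genomeB")
  types <- list(
    mk_type("t_two", c("s1", "s2")),
    mk_type("t_four", c("s1", "s2", "s3", "s4")),
    mk_type("t_tie", c("s5", "s6", "genomeA")),
    mk_type("t_uniq", "s3"))
  dm <- distribution_matrix(types, study, refs,
                            max_db_pid = c(t_two = 95, t_four = 100,
                                           t_tie = 92, t_uniq = 40))
  expect_equal(rownames(dm$matrix)[1], "t_four")
  # equal study counts (2): more total labels first
  expect_equal(rownames(dm$matrix)[2], "t_tie")
  expect_equal(rownames(dm$matrix)[3], "t_two")
  expect_equal(dm$unique_types, "t_uniq")
  expect_equal(unname(dm$k_summary[c("k1", "k2", "k4")]), c(4L, 3L, 1L))

  bad <- list(mk_type("t_bad", c("s1", "elsewhere")))
  expect_error(distribution_matrix(bad, study, refs), "unknown member label")
})
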