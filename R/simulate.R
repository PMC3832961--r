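# Seeded synthetic gene families, sample mixtures, reads and chimeras.
#
# Sequences evolve along a simulated tree under a two-parameter (K2P)
# nucleotide model; per-site rates are scaled down inside declared
# conserved blocks so that primer-able regions exist by construction.
# No indel process is simulated, so the true alignment is the gap-free
# sequence matrix itself.  All randomness flows from a single integer
# seed through one RNG stream.

#' Specification of a synthetic gene family
#'
#' @param n_taxa number of family members (>= 3).
#' @param tree_shape `"random_coalescent"` or `"birth_death"`.
#' @param mean_divergence mean root-to-tip path length,
#'   substitutions/site.
#' @param conserved_blocks data.frame with columns `start` (1-based),
#'   `length`, `rate` (multiplier in (0,1]); non-overlapping, inside the
#'   gene.
#' @param gene_length bp.
#' @param kappa transition/transversion rate ratio of the K2P model.
#' @param seed integer; fixes all randomness.
#' @return list of class `family_spec`.
#' @export
family_spec <- function(n_taxa = 24L, tree_shape = c("random_coalescent",
                                                     "birth_death"),
                        mean_divergence = 0.15,
                        conserved_blocks = data.frame(
                          start = c(101L, 601L), length = c(60L, 60L),
                          rate = c(0.02, 0.02)),
                        gene_length = 900L, kappa = 2, seed = 1L) {
  tree_shape <- match.arg(tree_shape)
  if (n_taxa < 3L) stop("n_taxa must be >= 3")
  if (nrow(conserved_blocks)) {
    stopifnot(all(conserved_blocks$rate > 0), all(conserved_blocks$rate <= 1))
    b <- conserved_blocks[order(conserved_blocks$start), ]
    ends <- b$start + b$length - 1L
    if (any(ends > gene_length) || any(b$start < 1L)) {
      stop("conserved block outside gene")
    }
    if (nrow(b) > 1L && any(b$start[-1L] <= ends[-nrow(b)])) {
      stop("conserved blocks overlap")
    }
  }
  structure(list(n_taxa = as.integer(n_taxa), tree_shape = tree_shape,
                 mean_divergence = mean_divergence,
                 conserved_blocks = conserved_blocks,
                 gene_length = as.integer(gene_length), kappa = kappa,
                 seed = as.integer(seed)),
            class = "family_spec")
}

# K2P substitution: given branch length d (expected subs/site * rate
# multiplier) and kappa, sample child base from parent base
k2p_probs <- function(d, kappa) {
  # rates scaled so total substitution rate is 1 per unit branch length
  beta <- 1 / (kappa + 2)
  alpha <- kappa * beta
  e1 <- exp(-4 * beta * d)
  e2 <- exp(-2 * (alpha + beta) * d)
  p_ts <- 0.25 + 0.25 * e1 - 0.5 * e2   # transition
  p_tv <- 0.25 - 0.25 * e1              # each transversion
  c(same = 1 - p_ts - 2 * p_tv, ts = p_ts, tv = p_tv)
}

TRANSITION_OF <- c(A = "G", G = "A", C = "T", T = "C")
TRANSVERSIONS_OF <- list(A = c("C", "T"), G = c("C", "T"),
                         C = c("A", "G"), T = c("A", "G"))

evolve_seq <- function(parent, d, rates, kappa) {
  n <- length(parent)
  child <- parent
  # per-site effective distance = d * rate multiplier; group sites by rate
  for (r in unique(rates)) {
    idx <- which(rates == r)
    p <- k2p_probs(d * r, kappa)
    u <- stats::runif(length(idx))
    ts <- u < p[["ts"]]
    tv1 <- !ts & u < p[["ts"]] + p[["tv"]]
    tv2 <- !ts & !tv1 & u < p[["ts"]] + 2 * p[["tv"]]
    child[idx[ts]] <- TRANSITION_OF[parent[idx[ts]]]
    for (b in BASES) {
      sel <- idx[tv1] [parent[idx[tv1]] == b]
      if (length(sel)) child[sel] <- TRANSVERSIONS_OF[[b]][1L]
      sel <- idx[tv2] [parent[idx[tv2]] == b]
      if (length(sel)) child[sel] <- TRANSVERSIONS_OF[[b]][2L]
    }
  }
  child
}

#' Simulate a gene family
#'
#' Evolves sequences down a simulated tree (coalescent or birth-death
#' shape, rescaled so the mean root-to-tip path equals
#' `mean_divergence`), with per-site rate multipliers inside conserved
#' blocks.
#'
#' @param spec a [family_spec].
#' @return list: `alignment` (gap-free `seq_aln`), `tree` (`phylo`),
#'   `sequences` (ungapped [seq_set], identical to the alignment rows).
#' @export
simulate_family <- function(spec = family_spec()) {
  with_seed(spec$seed, {
    tr <- if (spec$tree_shape == "random_coalescent") {
      ape::rcoal(spec$n_taxa)
    } else {
      ape::rphylo(spec$n_taxa, birth = 1, death = 0.2)
    }
    tr$tip.label <- sprintf("member_%02d", seq_len(spec$n_taxa))
    # rescale: mean root-to-tip path = mean_divergence
    depths <- ape::node.depth.edgelength(tr)[seq_len(spec$n_taxa)]
    md <- mean(depths)
    if (md > 0 && spec$mean_divergence > 0) {
      tr$edge.length <- tr$edge.length * spec$mean_divergence / md
    } else if (spec$mean_divergence == 0) {
      tr$edge.length[] <- 0
    }
    rates <- rep(1, spec$gene_length)
    cb <- spec$conserved_blocks
    for (k in seq_len(nrow(cb))) {
      rates[cb$start[k]:(cb$start[k] + cb$length[k] - 1L)] <- cb$rate[k]
    }
    root_seq <- sample(BASES, spec$gene_length, replace = TRUE)
    # conserved blocks are primer-able by construction: resample a block
    # until enough of its 18-mer windows satisfy the default primer screen
    for (k in seq_len(nrow(cb))) {
      idx <- cb$start[k]:(cb$start[k] + cb$length[k] - 1L)
      root_seq[idx] <- primerable_block(length(idx))
    }
    ntip <- spec$n_taxa
    nnode <- ntip + tr$Nnode
    seqs <- vector("list", nnode)
    seqs[[ntip + 1L]] <- root_seq
    pre <- stats::reorder(tr, "cladewise")   # parent precedes child
    for (e in seq_len(nrow(pre$edge))) {
      p <- pre$edge[e, 1L]; ch <- pre$edge[e, 2L]
      seqs[[ch]] <- evolve_seq(seqs[[p]], pre$edge.length[e], rates,
                               spec$kappa)
    }
    tipseqs <- vapply(seq_len(ntip), function(i) paste(seqs[[i]], collapse = ""),
                      character(1L))
    sequences <- seq_set(tr$tip.label, tipseqs, alphabet = "dna")
    list(alignment = as_alignment(sequences), tree = tr,
         sequences = sequences)
  })
}

#' Specification of synthetic sample mixtures
#'
#' @param n_samples number of samples.
#' @param inclusion_prob per-sample probability that each family member
#'   is present.
#' @param n_background composition-preserving shuffled decoys per sample.
#' @param n_chimeras midpoint chimeras spiked per sample.
#' @param read_length read length for [fragment_reads].
#' @param seed integer seed.
#' @return list of class `sample_spec`.
#' @export
sample_spec <- function(n_samples = 6L, inclusion_prob = 0.6,
                        n_background = 3L, n_chimeras = 1L,
                        read_length = 102L, seed = 1L) {
  stopifnot(inclusion_prob >= 0, inclusion_prob <= 1, n_background >= 0L,
            n_chimeras >= 0L)
  structure(list(n_samples = as.integer(n_samples),
                 inclusion_prob = inclusion_prob,
                 n_background = as.integer(n_background),
                 n_chimeras = as.integer(n_chimeras),
                 read_length = as.integer(read_length),
                 seed = as.integer(seed)),
            class = "sample_spec")
}

# sample a block whose 18-mer windows mostly pass the default primer
# thermodynamic screen (Tm in [45,62], hairpin <= 20 C, self-dimer within
# the one-third rule); draws from the ambient RNG stream
primerable_block <- function(len) {
  if (len < 18L) return(sample(BASES, len, replace = TRUE))
  params <- thermo_params()
  repeat {
    cand <- sample(BASES, len, replace = TRUE)
    s <- paste(cand, collapse = "")
    starts <- seq(1L, len - 17L)
    ok <- 0L
    for (st in starts) {
      w <- substr(s, st, st + 17L)
      tm <- tm_nn(w, params)
      if (tm < 45 || tm > 62) next
      if (hairpin_tm(w, params) > 20) next
      if (abs(duplex_dg(w, w, params)) > abs(full_duplex_dg(w, params)) / 3) next
      ok <- ok + 1L
    }
    if (ok >= max(6L, length(starts) %/% 3L)) return(cand)
  }
}

shuffle_seq <- function(seq) {
  paste(sample(strsplit(seq, "", fixed = TRUE)[[1L]]), collapse = "")
}

#' Build synthetic per-sample sequence mixtures with a truth table
#'
#' Each sample holds a random member subset, shuffled-composition
#' background decoys (the hardest non-specific case for a best-match
#' classifier) and optional midpoint chimeras whose halves come from two
#' members, drawn from different groups whenever the grouping allows.
#'
#' @param family result of [simulate_family].
#' @param spec a [sample_spec].
#' @param groups optional named vector: member id -> group id, recorded
#'   in the truth table and used to pick cross-group chimera donors.
#' @return list: `samples` (named list of [seq_set]), `truth`
#'   (data.frame: sample, seq_id, origin, source_id, group,
#'   chimera_breakpoint).
#' @export
make_samples <- function(family, spec = sample_spec(), groups = NULL) {
  members <- family$sequences
  if (spec$n_chimeras > 0L && length(members) < 2L) {
    stop("chimeras require at least 2 family members")
  }
  with_seed(spec$seed, {
    samples <- vector("list", spec$n_samples)
    names(samples) <- sprintf("sample_%02d", seq_len(spec$n_samples))
    truth <- list()
    for (s in seq_len(spec$n_samples)) {
      sname <- names(samples)[s]
      inc <- stats::runif(length(members)) < spec$inclusion_prob
      ids <- character(0L); seqs <- character(0L)
      for (i in which(inc)) {
        sid <- sprintf("%s|%s", sname, members$id[i])
        ids <- c(ids, sid); seqs <- c(seqs, members$seq[i])
        truth[[length(truth) + 1L]] <- data.frame(
          sample = sname, seq_id = sid, origin = "member",
          source_id = members$id[i],
          group = if (is.null(groups)) NA_character_ else
            unname(groups[members$id[i]]),
          chimera_breakpoint = NA_integer_, stringsAsFactors = FALSE)
      }
      for (b in seq_len(spec$n_background)) {
        donor <- sample(length(members), 1L)
        sid <- sprintf("%s|decoy_%02d", sname, b)
        ids <- c(ids, sid)
        seqs <- c(seqs, shuffle_seq(members$seq[donor]))
        truth[[length(truth) + 1L]] <- data.frame(
          sample = sname, seq_id = sid, origin = "background",
          source_id = members$id[donor], group = NA_character_,
          chimera_breakpoint = NA_integer_, stringsAsFactors = FALSE)
      }
      for (cidx in seq_len(spec$n_chimeras)) {
        pick <- pick_chimera_donors(members$id, groups)
        d1 <- pick[1L]; d2 <- pick[2L]
        s1 <- members$seq[match(d1, members$id)]
        s2 <- members$seq[match(d2, members$id)]
        bp <- nchar(s1) %/% 2L
        sid <- sprintf("%s|chimera_%02d", sname, cidx)
        ids <- c(ids, sid)
        seqs <- c(seqs, paste0(substr(s1, 1L, bp),
                               substr(s2, bp + 1L, nchar(s2))))
        truth[[length(truth) + 1L]] <- data.frame(
          sample = sname, seq_id = sid, origin = "chimera",
          source_id = paste(d1, d2, sep = "+"),
          group = if (is.null(groups)) NA_character_ else
            paste(groups[d1], groups[d2], sep = "+"),
          chimera_breakpoint = bp, stringsAsFactors = FALSE)
      }
      samples[[s]] <- if (length(ids)) {
        seq_set(ids, seqs, alphabet = "dna")
      } else {
        structure(list(id = character(0L), desc = character(0L),
                       seq = character(0L), alphabet = "dna", qual = NULL),
                  class = "seq_set")
      }
    }
    list(samples = samples, truth = do.call(rbind, truth))
  })
}

# prefer donors from different groups; fall back to any two members
pick_chimera_donors <- function(ids, groups) {
  if (!is.null(groups) && length(unique(groups[ids])) > 1L) {
    repeat {
      d <- sample(ids, 2L)
      if (groups[d[1L]] != groups[d[2L]]) return(d)
    }
  }
  sample(ids, 2L)
}

#' Fragment sequences into padded fixed-length reads
#'
#' Reads tile each source sequence with a core of
#' `read_len - head_pad - tail_pad` bases flanked by random synthetic
#' pads, so trimming with a matching [trim_spec] reconstructs exact
#' substrings of the source.
#'
#' @param sequences a [seq_set].
#' @param read_len total read length.
#' @param head_pad,tail_pad synthetic pad lengths, 5' and 3'.
#' @param seed integer seed (pads are random bases).
#' @param step tiling step; default the core length (non-overlapping).
#' @return [seq_set] of reads named `<source>:<start>` (0-based core
#'   start).
#' @export
fragment_reads <- function(sequences, read_len = 102L, head_pad = 4L,
                           tail_pad = 21L, seed = 1L, step = NULL) {
  core <- read_len - head_pad - tail_pad
  if (core <= 0L) stop("read_len must exceed head_pad + tail_pad")
  if (is.null(step)) step <- core
  with_seed(seed, {
    ids <- character(0L); seqs <- character(0L)
    for (i in seq_along(sequences$id)) {
      s <- sequences$seq[i]
      if (nchar(s) < core) {
        warning("sequence ", sequences$id[i], " shorter than read core; skipped")
        next
      }
      starts <- unique(c(seq(1L, nchar(s) - core + 1L, by = step),
                         nchar(s) - core + 1L))
      for (st in starts) {
        pad5 <- paste(sample(BASES, head_pad, replace = TRUE), collapse = "")
        pad3 <- paste(sample(BASES, tail_pad, replace = TRUE), collapse = "")
        ids <- c(ids, sprintf("%s:%d", sequences$id[i], st - 1L))
        seqs <- c(seqs, paste0(pad5, substr(s, st, st + core - 1L), pad3))
      }
    }
    seq_set(ids, seqs, alphabet = "dna")
  })
}
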