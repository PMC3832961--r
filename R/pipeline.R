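# Post-sequencing amplicon analysis: read trimming, contig length gates,
# translation, best-match classification into primer groups, chimera
# screening, >=90%-PID ortholog typing, novelty binning and cross-sample
# distribution tables.
#
# Alignment is an in-package affine-gap aligner (Biostrings
# pairwiseAlignment; BLOSUM62 for proteins, +2/-3 match/mismatch for
# nucleotides).  BLAST-style e-value gates are replaced by deterministic
# score + identity + coverage gates.

#' Read trimming/filtering specification
#'
#' Defaults mirror a typical fixed-length amplicon run: 4 bases clipped
#' from the 5' end and 21 from the 3' end of 102-base reads, leaving
#' 77-base reads.
#'
#' @param head_trim bases removed from the 5' end.
#' @param tail_trim bases removed from the 3' end.
#' @param min_len minimum post-trim length; shorter reads are dropped.
#' @param min_entropy bits/base; reads containing any 32-base window with
#'   Shannon entropy below this are dropped as low-complexity.
#' @param adapter_seqs character vector of adapter sequences.
#' @return list of class `trim_spec`.
#' @export
trim_spec <- function(head_trim = 4L, tail_trim = 21L, min_len = 77L,
                      min_entropy = 0.5, adapter_seqs = character(0L)) {
  stopifnot(head_trim >= 0L, tail_trim >= 0L, min_len >= 0L,
            min_entropy >= 0, min_entropy <= 2)
  structure(list(head_trim = head_trim, tail_trim = tail_trim,
                 min_len = min_len, min_entropy = min_entropy,
                 adapter_seqs = toupper(adapter_seqs)),
            class = "trim_spec")
}

shannon_entropy <- function(chars) {
  p <- table(chars) / length(chars)
  -sum(p * log2(p))
}

# lowest sliding-window entropy (window 32, step 8; plus whole read if
# shorter than the window)
min_window_entropy <- function(seq, window = 32L, step = 8L) {
  ch <- strsplit(seq, "", fixed = TRUE)[[1L]]
  n <- length(ch)
  if (n <= window) return(shannon_entropy(ch))
  starts <- unique(c(seq(1L, n - window + 1L, by = step), n - window + 1L))
  min(vapply(starts, function(s) shannon_entropy(ch[s:(s + window - 1L)]),
             numeric(1L)))
}

# adapter hit: exact 12-mer seed anywhere, then >=90% identity of the
# full adapter against the read region starting at the seed
matches_adapter <- function(seq, adapter) {
  seed_len <- min(12L, nchar(adapter))
  seed <- substr(adapter, 1L, seed_len)
  pos <- 1L
  repeat {
    hit <- regexpr(seed, substr(seq, pos, nchar(seq)), fixed = TRUE)
    if (hit < 0L) return(FALSE)
    at <- pos + as.integer(hit) - 1L
    region <- substr(seq, at, min(nchar(seq), at + nchar(adapter) - 1L))
    k <- nchar(region)
    a <- strsplit(region, "")[[1L]]
    b <- strsplit(substr(adapter, 1L, k), "")[[1L]]
    if (sum(a == b) / nchar(adapter) >= 0.9) return(TRUE)
    pos <- at + 1L
    if (pos > nchar(seq) - seed_len + 1L) return(FALSE)
  }
}

#' Trim and filter reads
#'
#' Applies, in order: the length gate (reads shorter than
#' `head_trim + tail_trim + min_len` are dropped), head/tail trimming,
#' adapter removal (any read containing an adapter is dropped), and the
#' low-complexity entropy filter.  Removal counts per reason are attached
#' as attribute `log`.
#'
#' @param reads a [seq_set] (FASTA or FASTQ origin).
#' @param spec a [trim_spec].
#' @return filtered, trimmed [seq_set].
#' @export
trim_and_filter <- function(reads, spec = trim_spec()) {
  need <- spec$head_trim + spec$tail_trim + spec$min_len
  lens <- nchar(reads$seq)
  if (all(lens < spec$head_trim + spec$tail_trim + 1L)) {
    stop("no reads survive: head+tail trim >= every read length")
  }
  log <- c(too_short = 0L, adapter = 0L, low_complexity = 0L, kept = 0L)
  keep <- logical(length(reads))
  trimmed <- character(length(reads))
  for (i in seq_along(reads$id)) {
    if (lens[i] < need) { log[["too_short"]] <- log[["too_short"]] + 1L; next }
    s <- substr(reads$seq[i], spec$head_trim + 1L, lens[i] - spec$tail_trim)
    if (length(spec$adapter_seqs) &&
        any(vapply(spec$adapter_seqs, matches_adapter, logical(1L),
                   seq = reads$seq[i]))) {
      log[["adapter"]] <- log[["adapter"]] + 1L
      next
    }
    if (min_window_entropy(s) < spec$min_entropy) {
      log[["low_complexity"]] <- log[["low_complexity"]] + 1L
      next
    }
    keep[i] <- TRUE
    trimmed[i] <- s
  }
  log[["kept"]] <- sum(keep)
  out <- reads[which(keep)]
  out$seq <- trimmed[keep]
  if (!is.null(out$qual)) {
    out$qual <- substr(reads$qual[keep], spec$head_trim + 1L,
                       lens[keep] - spec$tail_trim)
  }
  attr(out, "log") <- log
  out
}

#' Contig length gates
#'
#' Splits contigs into the reporting set (strictly longer than
#' `report_min`, default 250 bp) and the external-search subset (strictly
#' longer than `search_min`, default 500 bp).
#'
#' @param contigs a [seq_set].
#' @param report_min,search_min length cut-offs in bp (strict).
#' @return list with `reporting` and `external` [seq_set]s.
#' @export
length_gates <- function(contigs, report_min = 250L, search_min = 500L) {
  lens <- nchar(contigs$seq)
  list(reporting = contigs[which(lens > report_min)],
       external = contigs[which(lens > search_min)])
}

#' Translate the longest open reading frame of a contig
#'
#' Scans all six frames; an ORF is a maximal stop-free codon run (a start
#' codon is not required, since amplicons usually enter mid-gene), using
#' the bacterial code.  Ties are broken by frame order +1, +2, +3, -1,
#' -2, -3, then leftmost.  Contigs whose longest ORF is shorter than
#' `min_codons` return `NULL` (flagged for downstream exclusion).
#'
#' @param contig plain DNA string or one-record [seq_set].
#' @param min_codons minimum ORF length in codons (default 30).
#' @return list `(protein, frame, nt_start, nt_end)` or `NULL`; `frame`
#'   in {1,2,3,-1,-2,-3}, coordinates 0-based half-open on the plus
#'   strand of the input.
#' @export
translate_longest_orf <- function(contig, min_codons = 30L) {
  seq <- if (inherits(contig, "seq_set")) contig$seq[1L] else toupper(contig)
  n <- nchar(seq)
  best <- NULL
  frames <- list(c(1L, 1L), c(1L, 2L), c(1L, 3L), c(-1L, 1L), c(-1L, 2L),
                 c(-1L, 3L))
  for (fr in frames) {
    strand <- fr[1L]; off <- fr[2L]
    s <- if (strand == 1L) seq else reverse_complement(seq)
    ncod <- (nchar(s) - off + 1L) %/% 3L
    if (ncod < 1L) next
    codons <- substring(s, off + 3L * (0:(ncod - 1L)),
                        off + 3L * (0:(ncod - 1L)) + 2L)
    aa <- translate_codons(codons)
    # maximal stop-free runs
    is_stop <- aa == "*"
    r <- rle(is_stop)
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
    for (k in seq_along(r$values)) {
      if (r$values[k]) next
      len <- r$lengths[k]
      if (is.null(best) || len > best$len) {
        best <- list(len = len, strand = strand, off = off,
                     cod_start = starts[k], cod_end = ends[k],
                     protein = paste(aa[starts[k]:ends[k]], collapse = ""))
      }
    }
  }
  if (is.null(best) || best$len < min_codons) return(NULL)
  # nucleotide coordinates on the plus strand of the input
  s_start <- best$off + 3L * (best$cod_start - 1L)        # 1-based in frame seq
  s_end <- best$off + 3L * best$cod_end - 1L
  if (best$strand == 1L) {
    nt <- c(s_start - 1L, s_end)
  } else {
    nt <- c(n - s_end, n - s_start + 1L)
  }
  list(protein = best$protein,
       frame = best$strand * ((best$off - 1L) %% 3L + 1L),
       nt_start = nt[1L], nt_end = nt[2L])
}

# vectorised codon translation (bacterial/standard table; ambiguous
# codons that do not resolve become X)
translate_codons <- function(codons) {
  out <- GENETIC_CODE_VEC[codons]
  out[is.na(out)] <- "X"
  unname(out)
}

GENETIC_CODE_VEC <- {
  gc <- Biostrings::GENETIC_CODE
  stats::setNames(as.character(gc), names(gc))
}

#' Percent identity and coverage of a query/reference pair
#'
#' Global affine-gap alignment (BLOSUM62 for proteins, +2/-3 for DNA;
#' gap open 10, extend 0.5).  `pid` is 100 x identities over columns
#' where both sequences are non-gap; `query_coverage` is the fraction of
#' query residues sitting in such columns.  Novelty binning downstream
#' requires `query_coverage > 0.9`.
#'
#' @param query,ref residue strings (same alphabet).
#' @param alphabet `"protein"` or `"dna"`.
#' @return list `(pid, query_coverage, score)`.
#' @export
compute_pid <- function(query, ref, alphabet = c("protein", "dna")) {
  alphabet <- match.arg(alphabet)
  if (!nzchar(query) || !nzchar(ref)) stop("empty sequence in compute_pid")
  al <- align_pair(query, ref, alphabet)
  a <- strsplit(al$aligned_query, "")[[1L]]
  b <- strsplit(al$aligned_ref, "")[[1L]]
  both <- a != "-" & b != "-"
  n_both <- sum(both)
  pid <- if (n_both == 0L) 0 else 100 * sum(a[both] == b[both]) / n_both
  list(pid = pid, query_coverage = n_both / nchar(query), score = al$score)
}

align_pair <- function(query, ref, alphabet) {
  if (alphabet == "protein") {
    mat <- blosum62_matrix()
    q <- gsub("[*]", "X", query); r <- gsub("[*]", "X", ref)
    pa <- Biostrings::pairwiseAlignment(
      Biostrings::AAString(q), Biostrings::AAString(r),
      substitutionMatrix = mat, gapOpening = 10, gapExtension = 0.5,
      type = "global")
  } else {
    mat <- Biostrings::nucleotideSubstitutionMatrix(match = 2, mismatch = -3,
                                                    baseOnly = FALSE)
    pa <- Biostrings::pairwiseAlignment(
      Biostrings::DNAString(query), Biostrings::DNAString(ref),
      substitutionMatrix = mat, gapOpening = 10, gapExtension = 0.5,
      type = "global")
  }
  list(aligned_query = as.character(Biostrings::alignedPattern(pa)),
       aligned_ref = as.character(Biostrings::alignedSubject(pa)),
       score = Biostrings::score(pa))
}

blosum62_cache <- new.env(parent = emptyenv())
blosum62_matrix <- function() {
  if (is.null(blosum62_cache$m)) {
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    blosum62_cache$m <- e$BLOSUM62
  }
  blosum62_cache$m
}

#' Classify query proteins against a grouped reference database
#'
#' Best hit = highest alignment score, ties broken by higher pid then
#' lexicographic reference id; the hit's group label is inherited.
#' Queries whose best pid < 25 or coverage < 0.5 are labelled
#' `"non-specific"` (off-target amplification products).  Proteins not
#' strictly longer than `min_protein_len` get `passed_length_gate =
#' FALSE`.
#'
#' @param queries [seq_set] of proteins (ids unique).
#' @param reference_db [seq_set] of reference proteins.
#' @param ref_groups named character vector: reference id -> group id.
#' @param min_protein_len length gate in aa (strict; default 200).
#' @param sample_labels optional named vector: query id -> sample label.
#' @return data.frame of `classified_hit`: `query_id, sample_label,
#'   best_ref_id, group_id, pid, query_coverage, score,
#'   passed_length_gate`.
#' @export
classify <- function(queries, reference_db, ref_groups,
                     min_protein_len = 200L, sample_labels = NULL) {
  if (length(reference_db) == 0L) stop("empty reference database")
  rows <- vector("list", length(queries))
  for (i in seq_along(queries$id)) {
    q <- queries$seq[i]
    best <- NULL
    for (j in order(reference_db$id)) {
      r <- compute_pid(q, reference_db$seq[j], alphabet = queries$alphabet)
      cand <- list(ref = reference_db$id[j], pid = r$pid,
                   cov = r$query_coverage, score = r$score)
      if (is.null(best) || cand$score > best$score ||
          (cand$score == best$score && cand$pid > best$pid)) {
        best <- cand
      }
    }
    nonspec <- best$pid < 25 || best$cov < 0.5
    rows[[i]] <- data.frame(
      query_id = queries$id[i],
      sample_label = if (is.null(sample_labels)) NA_character_ else
        unname(sample_labels[queries$id[i]]),
      best_ref_id = if (nonspec) NA_character_ else best$ref,
      group_id = if (nonspec) "non-specific" else
        unname(ref_groups[best$ref]),
      pid = best$pid, query_coverage = best$cov, score = best$score,
      passed_length_gate = nchar(queries$seq[i]) > min_protein_len,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  class(out) <- c("classified_hits", "data.frame")
  out
}

#' Screen a contig for chimeric origin
#'
#' The contig is split at its midpoint and the halves classified
#' independently against the nucleotide reference database.  The verdict
#' is `"chimeric"` iff both halves hit with pid >= `min_half_pid` and
#' their best references carry different group labels; `"untestable"`
#' for contigs shorter than `min_len`.
#'
#' @param query plain DNA string or one-record [seq_set].
#' @param reference_db nucleotide [seq_set] with `ref_groups` labels.
#' @param ref_groups named character vector: reference id -> group id.
#' @param min_half_pid identity threshold per half (default 80).
#' @param min_len minimum testable contig length in nt (default 400).
#' @return list `(verdict, half_groups, half_pids)`; verdict one of
#'   `"chimeric"`, `"clean"`, `"untestable"`.
#' @export
chimera_screen <- function(query, reference_db, ref_groups,
                           min_half_pid = 80, min_len = 400L) {
  seq <- if (inherits(query, "seq_set")) query$seq[1L] else toupper(query)
  if (nchar(seq) < min_len) {
    return(list(verdict = "untestable", half_groups = c(NA, NA),
                half_pids = c(NA_real_, NA_real_)))
  }
  mid <- nchar(seq) %/% 2L
  halves <- c(substr(seq, 1L, mid), substr(seq, mid + 1L, nchar(seq)))
  grp <- c(NA_character_, NA_character_)
  pid <- c(NA_real_, NA_real_)
  for (h in 1:2) {
    best <- NULL
    for (j in order(reference_db$id)) {
      r <- compute_pid(halves[h], reference_db$seq[j], alphabet = "dna")
      if (is.null(best) || r$score > best$score ||
          (r$score == best$score && r$pid > best$pid)) {
        best <- list(ref = reference_db$id[j], pid = r$pid, score = r$score)
      }
    }
    pid[h] <- best$pid
    if (best$pid >= min_half_pid) grp[h] <- unname(ref_groups[best$ref])
  }
  chim <- !anyNA(grp) && grp[1L] != grp[2L]
  list(verdict = if (chim) "chimeric" else "clean",
       half_groups = grp, half_pids = pid)
}

#' Cluster proteins into >=90%-identity ortholog types
#'
#' Greedy centroid clustering: sequences are visited longest-first (ties
#' by id); each joins the first centroid with pid >= `threshold` and
#' coverage > 0.9, else founds a new type.  Afterwards every type is
#' verified all-pairs; a violating type is deterministically re-split by
#' a complete-linkage greedy pass over its members in visiting order.
#'
#' @param proteins [seq_set] of proteins.
#' @param labels named character vector: sequence id -> sample/genome
#'   label.
#' @param threshold percent identity threshold in (0, 100] (default 90).
#' @return list of `rdha_type`: `type_id, centroid_id, members`
#'   (data.frame id/label).
#' @export
cluster_types <- function(proteins, labels, threshold = 90) {
  if (threshold <= 0 || threshold > 100) stop("threshold outside (0,100]")
  ord <- order(-nchar(proteins$seq), proteins$id)
  ids <- proteins$id[ord]
  seqs <- proteins$seq[ord]
  centroids <- integer(0L)       # indices into ids/seqs
  assign_to <- integer(length(ids))
  for (i in seq_along(ids)) {
    placed <- FALSE
    for (ci in seq_along(centroids)) {
      r <- compute_pid(seqs[i], seqs[centroids[ci]], alphabet = "protein")
      if (r$pid >= threshold && r$query_coverage > 0.9) {
        assign_to[i] <- ci
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      centroids <- c(centroids, i)
      assign_to[i] <- length(centroids)
    }
  }
  # post-hoc all-pairs verification with deterministic complete-linkage split
  clusters <- split(seq_along(ids), assign_to)
  final <- list()
  for (cl in clusters) {
    subs <- list()
    for (i in cl) {
      placed <- FALSE
      for (k in seq_along(subs)) {
        ok <- all(vapply(subs[[k]], function(j) {
          r <- compute_pid(seqs[i], seqs[j], alphabet = "protein")
          r$pid >= threshold && r$query_coverage > 0.9
        }, logical(1L)))
        if (ok) { subs[[k]] <- c(subs[[k]], i); placed <- TRUE; break }
      }
      if (!placed) subs[[length(subs) + 1L]] <- i
    }
    final <- c(final, subs)
  }
  # order types by centroid (first member = longest) id for stability
  final <- final[order(vapply(final, function(x) ids[x[1L]], character(1L)))]
  lapply(seq_along(final), function(k) {
    idx <- final[[k]]
    structure(list(type_id = sprintf("type_%03d", k),
                   centroid_id = ids[idx[1L]],
                   members = data.frame(id = ids[idx],
                                        label = unname(labels[ids[idx]]),
                                        stringsAsFactors = FALSE)),
              class = "rdha_type")
  })
}

#' @export
print.rdha_type <- function(x, ...) {
  cat(sprintf("<rdha_type %s> centroid %s, %d member(s)\n", x$type_id,
              x$centroid_id, nrow(x$members)))
  invisible(x)
}

#' Bin query sequences by novelty against a reference database
#'
#' Bins on the maximum pid to the reference database (study-internal
#' matches excluded upstream): `identical` (pid = 100), `high_90_99`
#' (90 <= pid < 100), `novel_30_89` (30 <= pid < 90), `unassigned`
#' (pid < 30).
#'
#' @param max_pid_to_db numeric vector of per-query maximum pids.
#' @return list: `counts` (named integer), `fractions`.
#' @export
novelty_bins <- function(max_pid_to_db) {
  if (length(max_pid_to_db) &&
      (any(max_pid_to_db < 0) || any(max_pid_to_db > 100))) {
    stop("pid outside [0,100]")
  }
  bins <- cut(max_pid_to_db, breaks = c(-Inf, 30, 90, 100, Inf),
              labels = c("unassigned", "novel_30_89", "high_90_99",
                         "identical"),
              right = FALSE)
  bins[max_pid_to_db == 100] <- "identical"
  counts <- table(factor(bins, levels = c("identical", "high_90_99",
                                          "novel_30_89", "unassigned")))
  counts <- stats::setNames(as.integer(counts), names(counts))
  n <- sum(counts)
  list(counts = counts,
       fractions = if (n) counts / n else counts * 0)
}

#' Presence/absence distribution matrix of ortholog types
#'
#' Rows are types, columns the study samples followed by reference
#' genomes.  Rows are ordered by (number of study samples containing the
#' type, descending), then (total labels containing it, descending), then
#' type id.  Types present in exactly one study sample with no reference
#' member and `max_db_pid < 90` are flagged unique.
#'
#' @param types list of `rdha_type` from [cluster_types].
#' @param study_samples character vector of study sample labels (column
#'   order preserved).
#' @param reference_genomes character vector of reference labels.
#' @param max_db_pid optional named numeric: type_id -> max pid against
#'   the reference database (used for the unique flag).
#' @return list of class `distribution_matrix`: `matrix` (logical),
#'   `order_keys` (data.frame), `k_summary` (types present in >= k study
#'   samples), `unique_types`.
#' @export
distribution_matrix <- function(types, study_samples, reference_genomes,
                                max_db_pid = NULL) {
  all_cols <- c(study_samples, reference_genomes)
  for (tp in types) {
    bad <- setdiff(tp$members$label, all_cols)
    if (length(bad) || anyNA(tp$members$label)) {
      stop("unlabelled or unknown member label in ", tp$type_id,
           if (length(bad)) paste0(": ", paste(bad, collapse = ", ")))
    }
  }
  m <- matrix(FALSE, length(types), length(all_cols),
              dimnames = list(vapply(types, `[[`, character(1L), "type_id"),
                              all_cols))
  for (tp in types) m[tp$type_id, unique(tp$members$label)] <- TRUE
  n_study <- rowSums(m[, study_samples, drop = FALSE])
  n_total <- rowSums(m)
  o <- order(-n_study, -n_total, rownames(m))
  m <- m[o, , drop = FALSE]
  n_study <- n_study[o]; n_total <- n_total[o]
  ks <- seq_len(max(1L, length(study_samples)))
  k_summary <- stats::setNames(
    vapply(ks, function(k) sum(n_study >= k), integer(1L)),
    paste0("k", ks))
  uniq <- rownames(m)[n_study == 1L &
                        rowSums(m[, reference_genomes, drop = FALSE]) == 0L]
  if (!is.null(max_db_pid)) {
    uniq <- uniq[!is.na(max_db_pid[uniq]) & max_db_pid[uniq] < 90]
  }
  structure(list(matrix = m,
                 order_keys = data.frame(type_id = rownames(m),
                                         n_study = as.integer(n_study),
                                         n_total = as.integer(n_total),
                                         stringsAsFactors = FALSE),
                 k_summary = k_summary,
                 unique_types = uniq),
            class = "distribution_matrix")
}

#' @export
print.distribution_matrix <- function(x, ...) {
  cat(sprintf("<distribution_matrix> %d type(s) x %d label(s); unique: %d\n",
              nrow(x$matrix), ncol(x$matrix), length(x$unique_types)))
  print(x$k_summary)
  invisible(x)
}
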