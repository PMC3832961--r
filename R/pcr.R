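# In-silico PCR: binding-site discovery and amplicon enumeration.
#
# Matching is IUPAC-vs-IUPAC by expansion-set intersection, so degenerate
# primers and ambiguous target bases (N in contigs) both match
# permissively.  Coordinates are 0-based half-open on the plus strand;
# strand "+" means the primer sequence itself matches the plus-strand
# text, "-" that its reverse complement does.

# integer-bitmask scan: mismatch counts of `primer` at every offset of
# `target` (both already bit-encoded); returns an integer vector of
# length n_target - n_primer + 1
mismatch_profile <- function(pbits, tbits) {
  np <- length(pbits); nt <- length(tbits)
  if (np > nt) return(integer(0L))
  nw <- nt - np + 1L
  mm <- integer(nw)
  off <- 0L:(nw - 1L)
  for (i in seq_len(np)) {
    mm <- mm + as.integer(bitwAnd(pbits[i], tbits[off + i]) == 0L)
  }
  mm
}

#' Find primer binding sites on both strands of a target
#'
#' Reports every position where the primer matches with at most `max_mm`
#' mismatches and zero mismatches inside the 3' clamp (the final
#' `clamp_len` bases of the primer).  A primer longer than the target
#' yields an empty result.
#'
#' @param primer IUPAC DNA string (or a `degenerate_primer`).
#' @param target a [seq_set] element or plain string; DNA.
#' @param max_mm maximum mismatches outside the clamp rule (default 0).
#' @param clamp_len 3' clamp length with zero tolerated mismatches
#'   (default 3).
#' @return data.frame (class `binding_sites`): `target_id, start, end,
#'   strand, mismatches, three_prime_mismatches`, sorted by (start,
#'   strand).
#' @export
find_binding_sites <- function(primer, target, max_mm = 0L, clamp_len = 3L) {
  if (inherits(primer, "degenerate_primer")) primer <- primer$iupac_seq
  stopifnot(max_mm >= 0L, clamp_len >= 0L)
  tid <- "target"
  tseq <- target
  if (inherits(target, "seq_set")) {
    stopifnot(length(target) == 1L)
    tid <- target$id[1L]
    tseq <- target$seq[1L]
  }
  primer <- toupper(primer)
  tseq <- toupper(tseq)
  np <- nchar(primer)
  tbits <- iupac_bits(tseq)
  out <- list()
  for (strand in c("+", "-")) {
    pseq <- if (strand == "+") primer else reverse_complement(primer)
    pbits <- iupac_bits(pseq)
    mm <- mismatch_profile(pbits, tbits)
    if (length(mm) == 0L) next
    # clamp: the primer's 3'-most clamp_len bases; on "+" these sit at the
    # window's right edge, on "-" (revcomp written onto plus strand) at the
    # left edge
    cl <- min(clamp_len, np)
    if (cl > 0L) {
      cidx <- if (strand == "+") (np - cl + 1L):np else 1L:cl
      cmm <- integer(length(mm))
      off <- 0L:(length(mm) - 1L)
      for (i in cidx) {
        cmm <- cmm + as.integer(bitwAnd(pbits[i], tbits[off + i]) == 0L)
      }
    } else {
      cmm <- integer(length(mm))
    }
    keep <- which(mm <= max_mm & cmm == 0L)
    if (length(keep)) {
      out[[strand]] <- data.frame(
        target_id = tid,
        start = keep - 1L,       # 0-based
        end = keep - 1L + np,
        strand = strand,
        mismatches = mm[keep],
        three_prime_mismatches = cmm[keep],
        stringsAsFactors = FALSE
      )
    }
  }
  res <- if (length(out)) do.call(rbind, out) else data.frame(
    target_id = character(0L), start = integer(0L), end = integer(0L),
    strand = character(0L), mismatches = integer(0L),
    three_prime_mismatches = integer(0L), stringsAsFactors = FALSE)
  res <- res[order(res$start, res$strand), , drop = FALSE]
  rownames(res) <- NULL
  class(res) <- c("binding_sites", "data.frame")
  res
}

#' Predict amplicons of a primer pair on a target
#'
#' Enumerates every (left site, right site) combination where the two
#' primers sit on opposite strands, the right site starts at or after the
#' left site's end, and the outer product length is at most `max_len`.
#' Both orientations relative to the deposited strand are considered:
#' forward-on-plus with reverse-on-minus, and reverse-on-plus with
#' forward-on-minus.  All overlapping/nested products are reported.
#'
#' @param pair list with `fwd_seq`/`rev_seq` IUPAC strings (one row of a
#'   panel table works), or a `primer_pair`.
#' @param target one-record [seq_set] or plain DNA string.
#' @param max_mm,clamp_len per-primer matching tolerance
#'   (see [find_binding_sites]).
#' @param max_len maximum product length in bp (default 4000).
#' @return data.frame (class `amplicons`): `target_id, start, end, length,
#'   strand_layout, fwd_mm, rev_mm`, sorted by (start, length).
#' @export
amplify <- function(pair, target, max_mm = 0L, clamp_len = 3L,
                    max_len = 4000L) {
  fwd <- pair$fwd_seq %||% pair$forward$iupac_seq
  rev_ <- pair$rev_seq %||% pair$reverse$iupac_seq
  fsites <- find_binding_sites(fwd, target, max_mm, clamp_len)
  rsites <- find_binding_sites(rev_, target, max_mm, clamp_len)
  tid <- if (inherits(target, "seq_set")) target$id[1L] else "target"
  combos <- list(
    list(left = fsites[fsites$strand == "+", ],
         right = rsites[rsites$strand == "-", ],
         layout = "fwd+/rev-", lf = TRUE),
    list(left = rsites[rsites$strand == "+", ],
         right = fsites[fsites$strand == "-", ],
         layout = "rev+/fwd-", lf = FALSE)
  )
  rows <- list()
  for (cb in combos) {
    if (nrow(cb$left) == 0L || nrow(cb$right) == 0L) next
    for (i in seq_len(nrow(cb$left))) {
      L <- cb$left[i, ]
      ok <- cb$right$start >= L$end
      R <- cb$right[ok, , drop = FALSE]
      if (nrow(R) == 0L) next
      len <- R$end - L$start
      keep <- len <= max_len
      if (!any(keep)) next
      R <- R[keep, , drop = FALSE]
      len <- len[keep]
      rows[[length(rows) + 1L]] <- data.frame(
        target_id = tid, start = L$start, end = R$end, length = len,
        strand_layout = cb$layout,
        fwd_mm = if (cb$lf) L$mismatches else R$mismatches,
        rev_mm = if (cb$lf) R$mismatches else L$mismatches,
        stringsAsFactors = FALSE)
    }
  }
  res <- if (length(rows)) do.call(rbind, rows) else data.frame(
    target_id = character(0L), start = integer(0L), end = integer(0L),
    length = integer(0L), strand_layout = character(0L),
    fwd_mm = integer(0L), rev_mm = integer(0L), stringsAsFactors = FALSE)
  res <- res[order(res$start, res$length), , drop = FALSE]
  rownames(res) <- NULL
  class(res) <- c("amplicons", "data.frame")
  res
}

#' Screen a primer panel against a set of targets
#'
#' Runs [amplify] for every (panel row, target) and tabulates amplicon
#' counts, mirroring a per-sample "n positive of N primer sets" summary.
#'
#' @param panel a `panel_table` data.frame.
#' @param targets a [seq_set] of DNA sequences.
#' @param mode `"perfect"` (0 mismatches) or `"tolerant"`.
#' @param max_mm,clamp_len,max_len tolerant-mode matching parameters.
#' @return list of class `panel_screen`: `hits` (groups x targets integer
#'   matrix of amplicon counts), `summary` (per-target data.frame with
#'   `n_positive` and `n_total`), `mode`.
#' @export
screen_panel <- function(panel, targets, mode = c("perfect", "tolerant"),
                         max_mm = 2L, clamp_len = 3L, max_len = 4000L) {
  mode <- match.arg(mode)
  if (nrow(panel) == 0L) stop("empty panel")
  mm <- if (mode == "perfect") 0L else max_mm
  hits <- matrix(0L, nrow(panel), length(targets),
                 dimnames = list(panel$group_id, targets$id))
  for (g in seq_len(nrow(panel))) {
    for (t in seq_along(targets$id)) {
      amp <- amplify(panel[g, ], targets[t], max_mm = mm,
                     clamp_len = clamp_len, max_len = max_len)
      hits[g, t] <- nrow(amp)
    }
  }
  summary <- data.frame(
    target_id = targets$id,
    n_positive = colSums(hits > 0L),
    n_total = nrow(panel),
    stringsAsFactors = FALSE, row.names = NULL)
  structure(list(hits = hits, summary = summary, mode = mode),
            class = "panel_screen")
}

#' @export
print.panel_screen <- function(x, ...) {
  cat(sprintf("<panel_screen> mode=%s, %d group(s) x %d target(s)\n",
              x$mode, nrow(x$hits), ncol(x$hits)))
  for (i in seq_len(nrow(x$summary))) {
    cat(sprintf("  %-24s %d positive of %d primer sets\n",
                x$summary$target_id[i], x$summary$n_positive[i],
                x$summary$n_total[i]))
  }
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
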