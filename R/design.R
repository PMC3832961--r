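# Degenerate primer-pair design for one primer group.
#
# Candidate windows slide over the group alignment; a window is eligible
# only if it contains no gap in any member and its IUPAC consensus
# degeneracy stays under the cap.  Eligible windows are screened against
# the three thermodynamic constraints (Tm window, hairpin cap, dimer
# third-of-total-dG rule) and feasible forward/reverse combinations are
# ranked deterministically.

#' Design constraints for primer pairs
#'
#' Defaults encode the published screen: per-primer melting-temperature
#' range inside 40-65 C, hairpin Tm at most 25 C, and worst cross-dimer
#' |dG| at most one third of the weaker primer's full perfect-duplex |dG|.
#'
#' @param tm_min,tm_max allowed Tm window, degrees C.
#' @param hairpin_max maximum hairpin Tm, degrees C.
#' @param dimer_ratio maximum |worst dimer dG| / min full-duplex |dG|.
#' @param len_min,len_max primer length range, nt.
#' @param degeneracy_cap maximum primer degeneracy.
#' @param amp_min,amp_max expected amplicon length bounds, bp.
#' @param thermo_cap expansions sampled per primer for thermodynamic
#'   screening (exact below the cap).
#' @param dimer_cap expansions per primer entering the all-pairs dimer
#'   scan (evenly subsampled from the thermo set when above).
#' @param max_dimer_checks candidate pairs dimer-screened before giving
#'   up (candidates are visited in rank order, so only hopeless
#'   alignments hit the cap; unchecked candidates are reported in the
#'   diagnostics).
#' @param max_pairs maximum ranked pairs returned per group.
#' @return list of class `design_constraints`.
#' @export
design_constraints <- function(tm_min = 40, tm_max = 65, hairpin_max = 25,
                               dimer_ratio = 1 / 3, len_min = 18L,
                               len_max = 28L, degeneracy_cap = 512,
                               amp_min = 300L, amp_max = 1700L,
                               thermo_cap = 32L, dimer_cap = 8L,
                               max_dimer_checks = 100L, max_pairs = 20L) {
  structure(list(tm_min = tm_min, tm_max = tm_max, hairpin_max = hairpin_max,
                 dimer_ratio = dimer_ratio, len_min = len_min,
                 len_max = len_max, degeneracy_cap = degeneracy_cap,
                 amp_min = amp_min, amp_max = amp_max,
                 thermo_cap = thermo_cap, dimer_cap = dimer_cap,
                 max_dimer_checks = max_dimer_checks, max_pairs = max_pairs),
            class = "design_constraints")
}

# build a degenerate_primer record with thermodynamic summary
make_primer <- function(iupac_seq, orientation, params, thermo_cap, seed) {
  ex <- enumerate_expansions(iupac_seq, cap = thermo_cap, seed = seed)
  tms <- vapply(ex, tm_nn, numeric(1L), params = params)
  hp <- vapply(ex, hairpin_tm, numeric(1L), params = params)
  fd <- vapply(ex, full_duplex_dg, numeric(1L), params = params)
  structure(list(iupac_seq = iupac_seq, orientation = orientation,
                 degeneracy = degeneracy(iupac_seq),
                 tm_min = min(tms), tm_max = max(tms),
                 hairpin_tm = max(hp),
                 dg_full_duplex = max(fd),  # weakest duplex: conservative
                 expansions = ex),
            class = "degenerate_primer")
}

#' @export
print.degenerate_primer <- function(x, ...) {
  cat(sprintf("<degenerate_primer %s> %s deg=%g Tm=[%.1f,%.1f] hairpin=%.1f\n",
              x$orientation, x$iupac_seq, x$degeneracy, x$tm_min, x$tm_max,
              x$hairpin_tm))
  invisible(x)
}

# worst (most negative) cross-dimer dG over sampled expansion pairs;
# expansion lists are evenly subsampled to `cap` to bound the scan
worst_dimer_dg <- function(ex1, ex2, params, cap = 8L) {
  sub <- function(ex) {
    if (length(ex) <= cap) return(ex)
    ex[unique(round(seq(1L, length(ex), length.out = cap)))]
  }
  best <- 0
  for (a in sub(ex1)) for (b in sub(ex2)) {
    dg <- duplex_dg(a, b, params)
    if (dg < best) best <- dg
  }
  best
}

#' Design ranked degenerate primer pairs for a group alignment
#'
#' Every returned pair satisfies all constraints for both primers and
#' their worst cross-dimer.  Pairs are ranked by lower combined
#' degeneracy, then wider Tm headroom (distance of the pair's Tm range
#' from the window edges), then longer amplicon, ties by leftmost forward
#' coordinate.  An empty result carries per-constraint rejection counts in
#' attribute `diagnostics`.
#'
#' @param group_aln group `seq_aln` (>= 2 rows, nucleotide).
#' @param constraints a [design_constraints].
#' @param params a [thermo_params].
#' @param group_id label carried into the output.
#' @param seed seed for expansion sampling.
#' @return list of `primer_pair` objects (possibly empty), each with
#'   `group_id, forward, reverse, fwd_start, rev_end, expected_len`.
#' @export
design_pair <- function(group_aln, constraints = design_constraints(),
                        params = thermo_params(), group_id = 1L, seed = 1L) {
  if (length(group_aln) < 2L) stop("group alignment needs >= 2 rows")
  cn <- constraints
  m <- aln_matrix(group_aln)
  ncol_aln <- ncol(m)
  diag_counts <- c(gap = 0L, degeneracy = 0L, tm = 0L, hairpin = 0L,
                   dimer = 0L)
  # per-column gap flag, set size and IUPAC code; window checks then
  # reduce to cumulative sums and a substring of the code string
  col_gap <- logical(ncol_aln)
  col_size <- integer(ncol_aln)
  col_code <- character(ncol_aln)
  for (j in seq_len(ncol_aln)) {
    u <- unique(m[, j])
    col_gap[j] <- any(u == "-")
    if (!col_gap[j]) {
      col_size[j] <- length(u)
      col_code[j] <- iupac_code(u)
    } else {
      col_size[j] <- 1L
      col_code[j] <- "N"
    }
  }
  code_str <- paste(col_code, collapse = "")
  cum_gap <- cumsum(col_gap)
  cum_logsize <- cumsum(log(col_size))
  windows <- list()
  for (start in seq_len(ncol_aln)) {
    for (len in seq(cn$len_min, cn$len_max)) {
      end <- start + len - 1L
      if (end > ncol_aln) break
      if (cum_gap[end] - (if (start > 1L) cum_gap[start - 1L] else 0L) > 0L) {
        diag_counts[["gap"]] <- diag_counts[["gap"]] + 1L
        next
      }
      logdeg <- cum_logsize[end] -
        (if (start > 1L) cum_logsize[start - 1L] else 0)
      if (logdeg > log(cn$degeneracy_cap) + 1e-9) {
        diag_counts[["degeneracy"]] <- diag_counts[["degeneracy"]] + 1L
        next
      }
      windows[[length(windows) + 1L]] <-
        list(start = start, len = len,
             deg = prod(as.double(col_size[start:end])),
             consensus = substr(code_str, start, end))
    }
  }
  if (length(windows) == 0L) {
    return(structure(list(), diagnostics = diag_counts,
                     class = "primer_pair_set"))
  }
  # keep the least-degenerate windows per 50-column start bin so both ends
  # of the alignment stay represented, then thermo-screen the survivors
  degs <- vapply(windows, `[[`, numeric(1L), "deg")
  starts <- vapply(windows, `[[`, integer(1L), "start")
  bins <- (starts - 1L) %/% 50L
  keep <- unlist(lapply(split(order(degs, starts), bins[order(degs, starts)]),
                        utils::head, 8L), use.names = FALSE)
  windows <- windows[sort(keep)]
  o <- order(vapply(windows, `[[`, numeric(1L), "deg"),
             vapply(windows, `[[`, integer(1L), "start"))
  windows <- windows[o]
  screen_side <- function(win, orientation) {
    seqs <- if (orientation == "forward") win$consensus else
      reverse_complement(win$consensus)
    p <- make_primer(seqs, orientation, params, cn$thermo_cap, seed)
    if (p$tm_min < cn$tm_min || p$tm_max > cn$tm_max) {
      diag_counts[["tm"]] <<- diag_counts[["tm"]] + 1L
      return(NULL)
    }
    if (p$hairpin_tm > cn$hairpin_max) {
      diag_counts[["hairpin"]] <<- diag_counts[["hairpin"]] + 1L
      return(NULL)
    }
    # self-dimer pre-screen: a primer violating the ratio against its own
    # full duplex can never satisfy the pair rule (the pair cap is at most
    # ratio * |own full duplex|)
    p$dg_self_dimer <- worst_dimer_dg(p$expansions, p$expansions, params,
                                      cn$dimer_cap)
    if (abs(p$dg_self_dimer) > cn$dimer_ratio * abs(p$dg_full_duplex)) {
      diag_counts[["dimer"]] <<- diag_counts[["dimer"]] + 1L
      return(NULL)
    }
    p
  }
  fwd_ok <- list(); rev_ok <- list()
  for (w in windows) {
    pf <- screen_side(w, "forward")
    if (!is.null(pf)) fwd_ok[[length(fwd_ok) + 1L]] <- c(w, list(primer = pf))
    pr <- screen_side(w, "reverse")
    if (!is.null(pr)) rev_ok[[length(rev_ok) + 1L]] <- c(w, list(primer = pr))
  }
  # candidate pairs within amplicon bounds
  cand <- list()
  for (f in fwd_ok) {
    for (r in rev_ok) {
      rev_end <- r$start + r$len - 1L
      amp <- rev_end + 1L - f$start          # columns, outer span
      if (r$start < f$start + f$len) next    # windows must not overlap
      if (amp < cn$amp_min || amp > cn$amp_max) next
      cand[[length(cand) + 1L]] <- list(f = f, r = r, expected_len = amp)
    }
  }
  if (length(cand)) {
    key_deg <- vapply(cand, function(p) p$f$deg * p$r$deg, numeric(1L))
    key_head <- vapply(cand, function(p) {
      min(p$f$primer$tm_min, p$r$primer$tm_min) - cn$tm_min +
        cn$tm_max - max(p$f$primer$tm_max, p$r$primer$tm_max)
    }, numeric(1L))
    key_len <- vapply(cand, function(p) p$expected_len, numeric(1L))
    key_start <- vapply(cand, function(p) p$f$start, numeric(1L))
    cand <- cand[order(key_deg, -key_head, -key_len, key_start)]
  }
  pairs <- list()
  checked <- 0L
  for (p in cand) {
    if (length(pairs) >= cn$max_pairs) break
    if (checked >= cn$max_dimer_checks) break
    checked <- checked + 1L
    dim_fr <- worst_dimer_dg(p$f$primer$expansions, p$r$primer$expansions,
                             params, cn$dimer_cap)
    worst <- min(dim_fr, p$f$primer$dg_self_dimer, p$r$primer$dg_self_dimer)
    cap_dg <- cn$dimer_ratio * min(abs(p$f$primer$dg_full_duplex),
                                   abs(p$r$primer$dg_full_duplex))
    if (abs(worst) > cap_dg) {
      diag_counts[["dimer"]] <- diag_counts[["dimer"]] + 1L
      next
    }
    fwd <- p$f$primer; fwd$dg_worst_dimer <- worst
    rev_ <- p$r$primer; rev_$dg_worst_dimer <- worst
    pairs[[length(pairs) + 1L]] <- structure(
      list(group_id = group_id, forward = fwd, reverse = rev_,
           fwd_start = p$f$start - 1L,                  # 0-based columns
           rev_end = p$r$start - 1L + p$r$len,
           expected_len = p$expected_len),
      class = "primer_pair")
  }
  structure(pairs, diagnostics = diag_counts, class = "primer_pair_set")
}

#' @export
print.primer_pair <- function(x, ...) {
  cat(sprintf("<primer_pair group %s> %s / %s, %d bp\n", x$group_id,
              x$forward$iupac_seq, x$reverse$iupac_seq, x$expected_len))
  invisible(x)
}

#' Design a panel: one best pair per group
#'
#' Runs [design_pair] on each group's sub-alignment and keeps the
#' top-ranked pair, assembling a panel table ready for [write_panel] /
#' [screen_panel].
#'
#' @param aln master `seq_aln`.
#' @param groups list of `primer_group` from [partition_tree].
#' @param constraints a [design_constraints].
#' @param params a [thermo_params].
#' @param seed expansion-sampling seed.
#' @return list: `panel` (`panel_table` data.frame), `pairs` (named list
#'   of `primer_pair`), `failed` (group ids with no feasible pair).
#' @export
design_panel <- function(aln, groups, constraints = design_constraints(),
                         params = thermo_params(), seed = 1L) {
  rows <- list(); pairs <- list(); failed <- character(0L)
  for (g in groups) {
    gid <- as.character(g$group_id)
    if (length(g$member_ids) < 2L) { failed <- c(failed, gid); next }
    sub <- extract_group_alignment(aln, g)
    ps <- design_pair(sub, constraints, params, group_id = gid, seed = seed)
    if (length(ps) == 0L) { failed <- c(failed, gid); next }
    best <- ps[[1L]]
    pairs[[gid]] <- best
    rows[[gid]] <- data.frame(
      group_id = gid,
      fwd_seq = best$forward$iupac_seq,
      rev_seq = best$reverse$iupac_seq,
      tm_min_c = round(min(best$forward$tm_min, best$reverse$tm_min), 2L),
      tm_max_c = round(max(best$forward$tm_max, best$reverse$tm_max), 2L),
      expected_len_bp = best$expected_len,
      stringsAsFactors = FALSE)
  }
  panel <- if (length(rows)) do.call(rbind, rows) else
    stats::setNames(data.frame(matrix(nrow = 0L, ncol = 6L)), PANEL_COLUMNS)
  rownames(panel) <- NULL
  class(panel) <- c("panel_table", "data.frame")
  list(panel = panel, pairs = pairs, failed = failed)
}

#' Validate a panel against its design set (in-silico self-coverage)
#'
#' For each group, amplifies every member's ungapped sequence with the
#' group's pair in perfect-match mode and reports the covered fraction,
#' flagging members missed by their own group's primers.
#'
#' @param panel `panel_table` data.frame.
#' @param design_set [seq_set] of the family sequences (ungapped).
#' @param membership named character vector: sequence id -> group id.
#' @param clamp_len,max_len matching parameters (perfect-match mode).
#' @return data.frame per group: `group_id, n_members, n_amplified,
#'   coverage`, plus attribute `missed` (character vector of member ids).
#' @export
validate_panel <- function(panel, design_set, membership,
                           clamp_len = 3L, max_len = 4000L) {
  if (length(design_set) == 0L) stop("empty design set")
  unknown <- setdiff(unique(membership), panel$group_id)
  if (length(unknown)) {
    stop("group label(s) absent from panel: ", paste(unknown, collapse = ", "))
  }
  missed <- character(0L)
  rows <- list()
  for (gid in panel$group_id) {
    members <- names(membership)[membership == gid]
    members <- intersect(members, design_set$id)
    hit <- logical(length(members))
    for (i in seq_along(members)) {
      amp <- amplify(panel[panel$group_id == gid, ], design_set[members[i]],
                     max_mm = 0L, clamp_len = clamp_len, max_len = max_len)
      hit[i] <- nrow(amp) > 0L
    }
    missed <- c(missed, members[!hit])
    rows[[gid]] <- data.frame(group_id = gid, n_members = length(members),
                              n_amplified = sum(hit),
                              coverage = if (length(members)) mean(hit) else NA_real_,
                              stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "missed") <- missed
  out
}
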