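# IUPAC nucleotide code arithmetic.
#
# Codes are manipulated as 4-bit masks (A=1, C=2, G=4, T=8) so that set
# intersection, expansion and consensus all reduce to integer ops.

IUPAC_BITS <- c(
  A = 1L, C = 2L, G = 4L, T = 8L,
  R = 5L,  # A/G
  Y = 10L, # C/T
  S = 6L,  # C/G
  W = 9L,  # A/T
  K = 12L, # G/T
  M = 3L,  # A/C
  B = 14L, # C/G/T
  D = 13L, # A/G/T
  H = 11L, # A/C/T
  V = 7L,  # A/C/G
  N = 15L
)

# inverse lookup: bitmask (1..15) -> code
IUPAC_CODE_OF <- {
  x <- character(15L)
  x[IUPAC_BITS] <- names(IUPAC_BITS)
  x
}

BASES <- c("A", "C", "G", "T")

#' Expand one IUPAC code to its base set
#' @param code single IUPAC character.
#' @return character vector of plain bases (subset of A,C,G,T).
#' @export
iupac_expand <- function(code) {
  b <- IUPAC_BITS[[toupper(code)]]
  BASES[bitwAnd(b, c(1L, 2L, 4L, 8L)) > 0L]
}

#' IUPAC code for a base set
#' @param bases character vector, non-empty subset of A,C,G,T.
#' @return single IUPAC character whose expansion equals `bases`.
#' @export
iupac_code <- function(bases) {
  bases <- unique(toupper(bases))
  if (length(bases) == 0L) stop("empty base set has no IUPAC code")
  if (!all(bases %in% BASES)) {
    stop("base set may only contain A, C, G, T; got: ",
         paste(setdiff(bases, BASES), collapse = ", "))
  }
  IUPAC_CODE_OF[sum(IUPAC_BITS[bases])]
}

# string -> integer bitmask vector; errors on characters outside the table
iupac_bits <- function(seq) {
  ch <- strsplit(seq, "", fixed = TRUE)[[1L]]
  b <- IUPAC_BITS[ch]
  if (anyNA(b)) {
    bad <- which(is.na(b))[1L]
    stop(sprintf("invalid IUPAC character '%s' at position %d", ch[bad], bad))
  }
  unname(b)
}

#' Do two IUPAC codes match?
#'
#' Two codes match iff their expansion sets intersect: R matches A, G, N
#' and D, but not C or Y (the sets A/G and C/T are disjoint).
#'
#' @param primer_char,target_char single IUPAC DNA characters.
#' @return logical scalar.
#' @export
iupac_match <- function(primer_char, target_char) {
  p <- IUPAC_BITS[[toupper(primer_char)]]
  t <- IUPAC_BITS[[toupper(target_char)]]
  bitwAnd(p, t) > 0L
}

#' IUPAC consensus of per-column base sets
#'
#' Builds the minimal degenerate sequence covering every observed residue:
#' position i carries the unique IUPAC code whose expansion equals set i,
#' so the consensus matches every contributing sequence by construction.
#'
#' @param columns list of character vectors; each a non-empty subset of
#'   A,C,G,T (gaps must be resolved upstream).
#' @return IUPAC DNA string.
#' @export
iupac_consensus <- function(columns) {
  if (length(columns) == 0L) stop("no columns supplied")
  paste(vapply(columns, function(set) {
    if (any(set == "-")) stop("gap character in consensus column set")
    iupac_code(set)
  }, character(1L)), collapse = "")
}

#' Degeneracy of an IUPAC sequence
#'
#' Product over positions of the expansion-set sizes: the number of plain
#' DNA sequences the degenerate oligo represents.
#'
#' @param iupac_seq IUPAC DNA string.
#' @return integer (double if it would overflow).
#' @export
degeneracy <- function(iupac_seq) {
  if (!nzchar(iupac_seq)) stop("empty sequence has no degeneracy")
  bits <- iupac_bits(iupac_seq)
  sizes <- vapply(bits, function(b) sum(bitwAnd(b, c(1L, 2L, 4L, 8L)) > 0L),
                  integer(1L))
  prod(as.double(sizes))
}

#' Enumerate (or sample) the plain-DNA expansions of an IUPAC sequence
#'
#' When degeneracy is at most `cap` every expansion is returned in
#' lexicographic order.  Above the cap a seeded uniform sample of `cap`
#' distinct expansions is drawn, always including the lexicographically
#' first and last so the sampled set brackets the composition extremes.
#'
#' @param iupac_seq IUPAC DNA string.
#' @param cap maximum number of expansions to return (>= 1).
#' @param seed integer seed used only when sampling.
#' @return character vector of plain DNA strings.
#' @export
enumerate_expansions <- function(iupac_seq, cap = 512L, seed = 1L) {
  stopifnot(cap >= 1L)
  bits <- iupac_bits(iupac_seq)
  sets <- lapply(bits, function(b) BASES[bitwAnd(b, c(1L, 2L, 4L, 8L)) > 0L])
  deg <- prod(as.double(lengths(sets)))
  n <- length(sets)
  if (deg <= cap) {
    # expand.grid with the last position varying slowest-reversed gives
    # lexicographic order if we build from the right
    grid <- expand.grid(rev(sets), stringsAsFactors = FALSE)
    out <- do.call(paste0, rev(grid))
    return(sort(out, method = "radix"))
  }
  first <- paste(vapply(sets, `[`, character(1L), 1L), collapse = "")
  last <- paste(vapply(sets, function(s) s[length(s)], character(1L)),
                collapse = "")
  # index-based sampling without materialising the full expansion set
  sizes <- lengths(sets)
  decode <- function(k) { # k in 0..deg-1, mixed-radix, leftmost most significant
    out <- character(n)
    for (i in seq_len(n)) {
      j <- n - i + 1L
      out[j] <- sets[[j]][(k %% sizes[j]) + 1L]
      k <- k %/% sizes[j]
    }
    paste(out, collapse = "")
  }
  picked <- character(0L)
  with_seed(seed, {
    need <- cap - 2L
    seen <- new.env(hash = TRUE)
    while (length(picked) < need) {
      k <- floor(stats::runif(1L) * deg)
      s <- decode(k)
      if (s != first && s != last && !exists(s, envir = seen)) {
        assign(s, TRUE, envir = seen)
        picked <- c(picked, s)
      }
    }
  })
  sort(c(first, last, picked), method = "radix")
}

#' Reverse complement of a (possibly degenerate) DNA string
#' @param seq IUPAC DNA string.
#' @return IUPAC DNA string.
#' @export
reverse_complement <- function(seq) {
  comp <- chartr("ACGTRYSWKMBDHVN", "TGCAYRSWMKVHDBN", toupper(seq))
  paste(rev(strsplit(comp, "", fixed = TRUE)[[1L]]), collapse = "")
}

# run expr with a locally-scoped RNG state
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}
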