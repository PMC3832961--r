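# Nearest-neighbor oligonucleotide thermodynamics.
#
# Unified NN parameter set (SantaLucia-style dimer dH/dS with terminal
# initiation terms), entropic salt correction dS + 0.368*(N-1)*ln[Na_eq],
# divalent ions folded into an effective monovalent concentration
# Na_eq(mM) = mono + 120*sqrt(di).  Duplex Tm uses CT/4 for a primer
# annealing to its complement in excess-template terms; hairpins are
# unimolecular (no concentration term) with a fixed loop entropy penalty.

# dH kcal/mol, dS cal/(mol K); keys are the 16 plain dinucleotides
NN_DH <- c(
  AA = -7.9, TT = -7.9, AT = -7.2, TA = -7.2,
  CA = -8.5, TG = -8.5, GT = -8.4, AC = -8.4,
  CT = -7.8, AG = -7.8, GA = -8.2, TC = -8.2,
  CG = -10.6, GC = -9.8, GG = -8.0, CC = -8.0
)
NN_DS <- c(
  AA = -22.2, TT = -22.2, AT = -20.4, TA = -21.3,
  CA = -22.7, TG = -22.7, GT = -22.4, AC = -22.4,
  CT = -21.0, AG = -21.0, GA = -22.2, TC = -22.2,
  CG = -27.2, GC = -24.4, GG = -19.9, CC = -19.9
)
# terminal initiation terms
INIT_DH <- c(AT = 2.3, GC = 0.1)
INIT_DS <- c(AT = 4.1, GC = -2.8)

GAS_CONSTANT <- 1.9872  # cal/(mol K)

#' Thermodynamic parameter set
#'
#' Defaults reflect a standard degenerate-primer PCR mix: 50 mM monovalent
#' salt, 1.5 mM Mg2+, 0.5 uM of each primer, free energies evaluated at
#' 37 C.
#'
#' @param monovalent_salt mM (>= 0).
#' @param divalent_salt mM (>= 0).
#' @param primer_conc uM (> 0); total strand concentration of one primer.
#' @param dg_temperature degrees C at which dG values are reported.
#' @param loop_ds cal/(mol K) fixed hairpin-loop entropy penalty (< 0).
#' @return list of class `thermo_params`.
#' @export
thermo_params <- function(monovalent_salt = 50, divalent_salt = 1.5,
                          primer_conc = 0.5, dg_temperature = 37,
                          loop_ds = -18) {
  if (monovalent_salt < 0 || divalent_salt < 0) stop("salt must be >= 0")
  if (primer_conc <= 0) stop("primer_conc must be > 0")
  structure(list(monovalent_salt = monovalent_salt,
                 divalent_salt = divalent_salt,
                 primer_conc = primer_conc,
                 dg_temperature = dg_temperature,
                 loop_ds = loop_ds,
                 nn_parameter_set = "unified_nn_v1"),
            class = "thermo_params")
}

na_equivalent <- function(params) {
  (params$monovalent_salt + 120 * sqrt(params$divalent_salt)) / 1000  # M
}

# dinucleotide dH/dS sums for a plain-DNA string (no init terms)
nn_stack_sums <- function(seq) {
  n <- nchar(seq)
  if (n < 2L) return(c(dh = 0, ds = 0))
  di <- substring(seq, 1:(n - 1L), 2:n)
  c(dh = sum(NN_DH[di]), ds = sum(NN_DS[di]))
}

assert_plain_dna <- function(seq) {
  if (grepl("[^ACGT]", seq)) {
    bad <- regmatches(seq, regexpr("[^ACGT]", seq))
    stop(sprintf("ambiguity code '%s' not allowed here; expand the primer first",
                 bad))
  }
}

#' Nearest-neighbor melting temperature of a plain oligo
#'
#' Tm (degrees C) of the oligo against its perfect complement:
#' `Tm = 1000*dH / (dS_salt + R*ln(CT/4)) - 273.15`, where dH/dS sum the
#' unified NN dimer terms plus terminal initiation, and
#' `dS_salt = dS + 0.368*(N-1)*ln[Na_eq]`.
#'
#' @param seq plain DNA string, length >= 6, no ambiguity codes.
#' @param params a [thermo_params].
#' @return numeric, degrees C.
#' @export
tm_nn <- function(seq, params = thermo_params()) {
  seq <- toupper(seq)
  if (nchar(seq) < 6L) stop("tm_nn requires length >= 6")
  assert_plain_dna(seq)
  st <- nn_stack_sums(seq)
  ends <- c(substr(seq, 1L, 1L), substr(seq, nchar(seq), nchar(seq)))
  init_key <- ifelse(ends %in% c("A", "T"), "AT", "GC")
  dh <- st[["dh"]] + sum(INIT_DH[init_key])
  ds <- st[["ds"]] + sum(INIT_DS[init_key])
  ds <- ds + 0.368 * (nchar(seq) - 1L) * log(na_equivalent(params))
  ct <- params$primer_conc * 1e-6 / 4
  1000 * dh / (ds + GAS_CONSTANT * log(ct)) - 273.15
}

#' Melting-temperature range of a degenerate primer
#'
#' Minimum and maximum [tm_nn] over the primer's plain-DNA expansions;
#' exact when degeneracy <= `cap`, otherwise over a seeded sample of `cap`
#' expansions that always includes the lexicographic extremes.
#'
#' @param iupac_seq IUPAC DNA string.
#' @param params a [thermo_params].
#' @param cap expansion cap (default 512).
#' @param seed sampling seed.
#' @return named numeric `c(tm_min=, tm_max=)`.
#' @export
tm_range_degenerate <- function(iupac_seq, params = thermo_params(),
                                cap = 512L, seed = 1L) {
  ex <- enumerate_expansions(iupac_seq, cap = cap, seed = seed)
  tms <- vapply(ex, tm_nn, numeric(1L), params = params)
  c(tm_min = min(tms), tm_max = max(tms))
}

revcomp_plain <- function(seq) {
  paste(rev(strsplit(chartr("ACGT", "TGCA", seq), "", fixed = TRUE)[[1L]]),
        collapse = "")
}

#' Hairpin melting temperature
#'
#' Scans every intramolecular stem with stem length at least 3 bp and
#' loop at least 3 nt: positions `i..i+k-1` paired antiparallel with
#' `j-k+1..j`.
#' Stem dH/dS come from the NN table (salt-corrected over the stem); a
#' fixed loop entropy penalty (`params$loop_ds`) closes the loop.  The
#' best (highest-Tm) stem is reported; `-Inf` when no stem exists.
#'
#' @param seq plain DNA string, length >= 8.
#' @param params a [thermo_params].
#' @return numeric degrees C, or `-Inf` when the oligo cannot fold.
#' @export
hairpin_tm <- function(seq, params = thermo_params()) {
  seq <- toupper(seq)
  if (nchar(seq) < 8L) stop("hairpin_tm requires length >= 8")
  assert_plain_dna(seq)
  ch <- strsplit(seq, "", fixed = TRUE)[[1L]]
  comp <- chartr("ACGT", "TGCA", seq)
  compch <- strsplit(comp, "", fixed = TRUE)[[1L]]
  n <- length(ch)
  best <- -Inf
  lnNa <- log(na_equivalent(params))
  for (i in seq_len(n)) {
    for (j in seq(i, n)) {
      # grow the stem inward from the (i, j) ends while bases pair
      t <- 0L
      while (i + t < j - t && ch[i + t] == compch[j - t]) t <- t + 1L
      if (t < 3L) next
      for (k in 3L:t) {
        if (j - i - 2L * k + 1L < 3L) break  # loop shorter than 3 nt
        stem <- substr(seq, i, i + k - 1L)
        st <- nn_stack_sums(stem)
        ds <- st[["ds"]] + 0.368 * (k - 1L) * lnNa + params$loop_ds
        tm <- 1000 * st[["dh"]] / ds - 273.15
        if (tm > best) best <- tm
      }
    }
  }
  best
}

#' Most stable duplex free energy between two oligos
#'
#' Slides `seq1` (5'->3') along the reverse of `seq2` over every ungapped
#' antiparallel offset, finds contiguous Watson-Crick complementary
#' stretches of >= 2 bp, and sums NN stacking dG over each stretch
#' (salt-corrected entropy, evaluated at `params$dg_temperature`).  The
#' most negative per-offset total is returned; 0 when no stretch exists
#' anywhere.  The full perfect duplex used by the dimer rule equals
#' `duplex_dg(seq, reverse_complement(seq))` at the zero offset, which
#' [full_duplex_dg] computes directly.
#'
#' @param seq1,seq2 plain DNA strings, each 5'->3'.
#' @param params a [thermo_params].
#' @return numeric kcal/mol (<= 0).
#' @export
duplex_dg <- function(seq1, seq2, params = thermo_params()) {
  seq1 <- toupper(seq1); seq2 <- toupper(seq2)
  assert_plain_dna(seq1); assert_plain_dna(seq2)
  a <- strsplit(seq1, "", fixed = TRUE)[[1L]]
  # antiparallel register: reverse seq2 and ask for complementarity
  b <- rev(strsplit(chartr("ACGT", "TGCA", seq2), "", fixed = TRUE)[[1L]])
  n1 <- length(a); n2 <- length(b)
  if (n1 < 2L || n2 < 2L) return(0)
  tK <- params$dg_temperature + 273.15
  lnNa <- log(na_equivalent(params))
  # a stretch of k matches contributes k-1 NN stacks, each with a
  # per-stack salt-corrected dG37, so the per-offset total is the sum of
  # per-stack dG over adjacent matched pairs: diagonal sums of the
  # shifted match matrix
  di <- substring(seq1, 1:(n1 - 1L), 2:n1)
  g <- NN_DH[di] - tK * (NN_DS[di] + 0.368 * lnNa) / 1000
  M <- outer(a, b, "==")
  S <- M[-n1, -n2, drop = FALSE] & M[-1L, -1L, drop = FALSE]
  if (!any(S)) return(0)
  W <- S * g                               # g recycles down rows
  offs <- row(S) - col(S)
  sums <- tapply(W[S], offs[S], sum)
  min(0, min(sums))
}

#' Full perfect-duplex free energy of an oligo
#' @param seq plain DNA string.
#' @param params a [thermo_params].
#' @return numeric kcal/mol.
#' @export
full_duplex_dg <- function(seq, params = thermo_params()) {
  seq <- toupper(seq)
  assert_plain_dna(seq)
  st <- nn_stack_sums(seq)
  tK <- params$dg_temperature + 273.15
  ds <- st[["ds"]] + 0.368 * (nchar(seq) - 1L) * log(na_equivalent(params))
  st[["dh"]] - tK * ds / 1000
}
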