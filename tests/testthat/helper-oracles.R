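# Independent brute-force oracles.  These deliberately avoid the package's
# own code paths: plain loops, exhaustive enumeration, no shared helpers.

# patristic distance by explicit path enumeration through the edge list
oracle_patristic <- function(tree) {
  n <- length(tree$tip.label)
  nn <- n + tree$Nnode
  adj <- vector("list", nn)
  for (e in seq_len(nrow(tree$edge))) {
    a <- tree$edge[e, 1]; b <- tree$edge[e, 2]; w <- tree$edge.length[e]
    adj[[a]] <- rbind(adj[[a]], c(b, w))
    adj[[b]] <- rbind(adj[[b]], c(a, w))
  }
  dist_from <- function(src) {
    d <- rep(NA_real_, nn); d[src] <- 0
    queue <- src
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      for (r in seq_len(NROW(adj[[v]]))) {
        u <- adj[[v]][r, 1]
        if (is.na(d[u])) { d[u] <- d[v] + adj[[v]][r, 2]; queue <- c(queue, u) }
      }
    }
    d
  }
  out <- matrix(0, n, n, dimnames = list(tree$tip.label, tree$tip.label))
  for (i in seq_len(n)) out[i, ] <- dist_from(i)[seq_len(n)]
  out
}

# minimal clade-partition size by exhaustive recursion: each node is either
# one group (if its leaf set satisfies pred) or split into its children
oracle_min_clade_partition <- function(tree, pred) {
  n <- length(tree$tip.label)
  kids <- vector("list", n + tree$Nnode)
  for (e in seq_len(nrow(tree$edge))) {
    kids[[tree$edge[e, 1]]] <- c(kids[[tree$edge[e, 1]]], tree$edge[e, 2])
  }
  leaves_of <- function(v) {
    if (v <= n) return(tree$tip.label[v])
    unlist(lapply(kids[[v]], leaves_of))
  }
  best <- function(v) {
    own <- if (pred(leaves_of(v))) 1L else Inf
    if (v <= n) return(own)
    min(own, sum(vapply(kids[[v]], best, numeric(1))))
  }
  best(n + 1L)
}

# exhaustive binding-site scan over every offset and strand, IUPAC sets
oracle_sites <- function(primer, target, max_mm, clamp_len) {
  expand1 <- function(ch) {
    tab <- list(A = "A", C = "C", G = "G", T = "T", R = c("A", "G"),
                Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
                K = c("G", "T"), M = c("A", "C"), B = c("C", "G", "T"),
                D = c("A", "G", "T"), H = c("A", "C", "T"),
                V = c("A", "C", "G"), N = c("A", "C", "G", "T"))
    tab[[ch]]
  }
  rc <- function(s) paste(rev(strsplit(chartr("ACGTRYSWKMBDHVN",
                                              "TGCAYRSWMKVHDBN", s),
                                       "")[[1]]), collapse = "")
  tch <- strsplit(target, "")[[1]]
  np <- nchar(primer)
  rows <- NULL
  for (strand in c("+", "-")) {
    p <- if (strand == "+") primer else rc(primer)
    pch <- strsplit(p, "")[[1]]
    for (s in seq_len(nchar(target) - np + 1)) {
      mm <- 0; cmm <- 0
      for (k in seq_len(np)) {
        hit <- length(intersect(expand1(pch[k]), expand1(tch[s + k - 1]))) > 0
        if (!hit) {
          mm <- mm + 1
          # clamp indices: 3' end of the primer
          in_clamp <- if (strand == "+") k > np - clamp_len else k <= clamp_len
          if (in_clamp) cmm <- cmm + 1
        }
      }
      if (mm <= max_mm && cmm == 0) {
        rows <- rbind(rows, data.frame(start = s - 1, end = s - 1 + np,
                                       strand = strand, mismatches = mm,
                                       stringsAsFactors = FALSE))
      }
    }
  }
  if (is.null(rows)) {
    rows <- data.frame(start = integer(0), end = integer(0),
                       strand = character(0), mismatches = integer(0))
  }
  rows[order(rows$start, rows$strand), , drop = FALSE]
}

# exhaustive amplicon enumeration from oracle site lists
oracle_amplicons <- function(fwd, rev, target, max_mm, clamp_len, max_len) {
  fs <- oracle_sites(fwd, target, max_mm, clamp_len)
  rs <- oracle_sites(rev, target, max_mm, clamp_len)
  rows <- NULL
  combos <- list(list(fs[fs$strand == "+", ], rs[rs$strand == "-", ]),
                 list(rs[rs$strand == "+", ], fs[fs$strand == "-", ]))
  for (cb in combos) {
    L <- cb[[1]]; R <- cb[[2]]
    if (nrow(L) == 0 || nrow(R) == 0) next
    for (i in seq_len(nrow(L))) for (j in seq_len(nrow(R))) {
      if (R$start[j] >= L$end[i] && R$end[j] - L$start[i] <= max_len) {
        rows <- rbind(rows, data.frame(start = L$start[i], end = R$end[j],
                                       length = R$end[j] - L$start[i]))
      }
    }
  }
  if (is.null(rows)) {
    rows <- data.frame(start = integer(0), end = integer(0),
                       length = integer(0))
  }
  rows <- rows[order(rows$start, rows$length), , drop = FALSE]
  rownames(rows) <- NULL
  rows
}

# brute-force best hairpin Tm over all (i, j, k) stem triplets
oracle_hairpin <- function(seq, loop_ds = -18, na_eq = (50 + 120 * sqrt(1.5)) / 1000) {
  dh_tab <- c(AA = -7.9, TT = -7.9, AT = -7.2, TA = -7.2, CA = -8.5,
              TG = -8.5, GT = -8.4, AC = -8.4, CT = -7.8, AG = -7.8,
              GA = -8.2, TC = -8.2, CG = -10.6, GC = -9.8, GG = -8.0,
              CC = -8.0)
  ds_tab <- c(AA = -22.2, TT = -22.2, AT = -20.4, TA = -21.3, CA = -22.7,
              TG = -22.7, GT = -22.4, AC = -22.4, CT = -21.0, AG = -21.0,
              GA = -22.2, TC = -22.2, CG = -27.2, GC = -24.4, GG = -19.9,
              CC = -19.9)
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  ch <- strsplit(seq, "")[[1]]
  n <- length(ch)
  best <- -Inf
  for (i in seq_len(n)) for (j in seq_len(n)) for (k in 3:((n %/% 2) + 1)) {
    if (i + k - 1 >= j - k + 1) next
    if ((j - k + 1) - (i + k - 1) - 1 < 3) next      # loop length
    if (j > n) next
    ok <- all(vapply(0:(k - 1), function(t) ch[i + t] == comp[ch[j - t]],
                     logical(1)))
    if (!ok) next
    stem <- substr(seq, i, i + k - 1)
    di <- substring(stem, 1:(k - 1), 2:k)
    dh <- sum(dh_tab[di]); ds <- sum(ds_tab[di])
    ds <- ds + 0.368 * (k - 1) * log(na_eq) + loop_ds
    tm <- 1000 * dh / ds - 273.15
    if (tm > best) best <- tm
  }
  best
}

# exhaustive duplex dG over all antiparallel offsets
oracle_duplex <- function(s1, s2, temp_c = 37, na_eq = (50 + 120 * sqrt(1.5)) / 1000) {
  dh_tab <- c(AA = -7.9, TT = -7.9, AT = -7.2, TA = -7.2, CA = -8.5,
              TG = -8.5, GT = -8.4, AC = -8.4, CT = -7.8, AG = -7.8,
              GA = -8.2, TC = -8.2, CG = -10.6, GC = -9.8, GG = -8.0,
              CC = -8.0)
  ds_tab <- c(AA = -22.2, TT = -22.2, AT = -20.4, TA = -21.3, CA = -22.7,
              TG = -22.7, GT = -22.4, AC = -22.4, CT = -21.0, AG = -21.0,
              GA = -22.2, TC = -22.2, CG = -27.2, GC = -24.4, GG = -19.9,
              CC = -19.9)
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  a <- strsplit(s1, "")[[1]]
  b2 <- rev(strsplit(s2, "")[[1]])   # antiparallel register
  n1 <- length(a); n2 <- length(b2)
  tK <- temp_c + 273.15
  best <- 0
  for (off in (-(n2 - 1)):(n1 - 1)) {
    lo <- max(1, 1 + off); hi <- min(n1, n2 + off)
    if (hi - lo + 1 < 2) next
    paired <- vapply(lo:hi, function(i) a[i] == comp[b2[i - off]], logical(1))
    total <- 0
    run_start <- NULL
    for (t in seq_along(paired)) {
      if (paired[t] && is.null(run_start)) run_start <- t
      if ((!paired[t] || t == length(paired)) && !is.null(run_start)) {
        run_end <- if (paired[t]) t else t - 1
        if (run_end - run_start >= 1) {
          stretch <- paste(a[(lo:hi)[run_start:run_end]], collapse = "")
          k <- nchar(stretch)
          di <- substring(stretch, 1:(k - 1), 2:k)
          dh <- sum(dh_tab[di])
          ds <- sum(ds_tab[di]) + 0.368 * (k - 1) * log(na_eq)
          total <- total + dh - tK * ds / 1000
        }
        run_start <- NULL
      }
    }
    if (total < best) best <- total
  }
  best
}

# brute-force 6-frame longest-ORF finder
oracle_longest_orf <- function(seq, min_codons = 30) {
  code <- Biostrings::GENETIC_CODE
  rc <- function(s) paste(rev(strsplit(chartr("ACGT", "TGCA", s), "")[[1]]),
                          collapse = "")
  best <- NULL
  frames <- list(c("+", 1), c("+", 2), c("+", 3), c("-", 1), c("-", 2),
                 c("-", 3))
  for (fr in frames) {
    s <- if (fr[[1]] == "+") seq else rc(seq)
    off <- as.integer(fr[[2]])
    aa <- character(0)
    p <- off
    while (p + 2 <= nchar(s)) {
      cd <- substr(s, p, p + 2)
      aa <- c(aa, if (cd %in% names(code)) code[[cd]] else "X")
      p <- p + 3
    }
    cur <- character(0)
    flush <- function(cur) {
      if (length(cur) > length(best %||% character(0))) cur else best
    }
    for (x in aa) {
      if (x == "*") { best <- flush(cur); cur <- character(0) }
      else cur <- c(cur, x)
    }
    best <- flush(cur)
  }
  if (is.null(best) || length(best) < min_codons) return(NULL)
  paste(best, collapse = "")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# exhaustive check: can `sets` of sequences be covered by `k` cliques under
# the all-pairs >=threshold relation?  Returns the minimal clique count.
oracle_min_clique_cover <- function(pids, threshold) {
  n <- nrow(pids)
  ok <- pids >= threshold
  diag(ok) <- TRUE
  # try all assignments of n items into at most n groups (n <= 6)
  best <- n
  assign_next <- function(assign, ngrp) {
    i <- length(assign) + 1
    if (i > n) { best <<- min(best, ngrp); return(invisible()) }
    if (ngrp >= best) return(invisible())
    for (g in seq_len(ngrp + 1)) {
      members <- which(assign == g)
      if (all(ok[i, members])) assign_next(c(assign, g), max(ngrp, g))
    }
  }
  assign_next(integer(0), 0)
  best
}

random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                       replace = TRUE), collapse = "")

random_protein <- function(n) {
  paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], n, replace = TRUE),
        collapse = "")
}
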