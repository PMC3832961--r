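# Sequence containers and format I/O (FASTA/FASTQ/Newick/panel TSV).
#
# Sequences are held in a light S3 container (`seq_set`): parallel vectors
# of id / description / residues plus an alphabet tag, with optional
# Phred+33 quality strings for FASTQ input.  Parsing of FASTA/FASTQ is
# delegated to Biostrings; validation (alphabet, uniqueness, case and U->T
# normalisation) happens here so error messages name the offending record.

DNA_CHARS <- c(names(IUPAC_BITS), "-")
PROTEIN_CHARS <- c(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1L]], "X", "*", "-")

PANEL_COLUMNS <- c("group_id", "fwd_seq", "rev_seq",
                   "tm_min_c", "tm_max_c", "expected_len_bp")

#' Construct a sequence set
#'
#' @param id character vector of unique, non-empty identifiers.
#' @param seq character vector of residue strings (same length as `id`).
#' @param alphabet `"dna"` or `"protein"`.
#' @param desc optional descriptions.
#' @param qual optional Phred+33 quality strings (DNA/FASTQ only).
#' @param gapped allow `-` characters (alignment rows).
#' @return object of class `seq_set`.
#' @export
seq_set <- function(id, seq, alphabet = c("dna", "protein"),
                    desc = NULL, qual = NULL, gapped = FALSE) {
  alphabet <- match.arg(alphabet)
  id <- as.character(id)
  seq <- toupper(as.character(seq))
  if (length(id) != length(seq)) stop("id and seq lengths differ")
  if (any(!nzchar(id))) stop("empty sequence id")
  if (anyDuplicated(id)) {
    stop("duplicate sequence id: ", id[duplicated(id)][1L])
  }
  if (alphabet == "dna" && any(grepl("U", seq, fixed = TRUE))) {
    warning("'U' residues mapped to 'T'")
    seq <- gsub("U", "T", seq, fixed = TRUE)
  }
  allowed <- if (alphabet == "dna") DNA_CHARS else PROTEIN_CHARS
  if (!gapped) allowed <- setdiff(allowed, "-")
  for (i in seq_along(seq)) {
    ch <- strsplit(seq[i], "", fixed = TRUE)[[1L]]
    bad <- which(!(ch %in% allowed))
    if (length(bad)) {
      stop(sprintf("record '%s': illegal %s character '%s' at position %d",
                   id[i], alphabet, ch[bad[1L]], bad[1L]))
    }
  }
  if (is.null(desc)) desc <- rep("", length(id))
  structure(list(id = id, desc = as.character(desc), seq = seq,
                 alphabet = alphabet, qual = qual),
            class = "seq_set")
}

#' @export
length.seq_set <- function(x) length(x$id)

#' @export
`[.seq_set` <- function(x, i) {
  if (is.character(i)) i <- match(i, x$id)
  if (anyNA(i)) stop("unknown sequence id in subset")
  structure(list(id = x$id[i], desc = x$desc[i], seq = x$seq[i],
                 alphabet = x$alphabet,
                 qual = if (is.null(x$qual)) NULL else x$qual[i]),
            class = class(x))
}

#' @export
print.seq_set <- function(x, ...) {
  cat(sprintf("<seq_set> %d %s sequence(s)\n", length(x), x$alphabet))
  n <- min(6L, length(x))
  for (i in seq_len(n)) {
    s <- x$seq[i]
    cat(sprintf("  %-20s %5d  %s%s\n", x$id[i], nchar(s),
                substr(s, 1L, 40L), if (nchar(s) > 40L) "..." else ""))
  }
  if (length(x) > n) cat(sprintf("  ... and %d more\n", length(x) - n))
  invisible(x)
}

#' Read sequences from FASTA or FASTQ
#'
#' Residues are upper-cased on ingestion; in DNA mode `U` is mapped to `T`
#' with a warning.  FASTQ (auto-detected from a leading `@`, or forced via
#' `format`) retains Phred+33 qualities for downstream trimming.
#'
#' @param path file path.
#' @param alphabet `"dna"` or `"protein"` (FASTQ implies DNA).
#' @param format `"auto"`, `"fasta"` or `"fastq"`.
#' @return a [seq_set] in file order.
#' @export
read_sequences <- function(path, alphabet = c("dna", "protein"),
                           format = c("auto", "fasta", "fastq")) {
  alphabet <- match.arg(alphabet)
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    first <- readLines(path, n = 1L)
    if (length(first) == 0L) stop("empty file: ", path)
    format <- if (startsWith(first, "@")) "fastq" else "fasta"
  }
  if (format == "fastq" && alphabet != "dna") {
    stop("FASTQ input is only supported for the dna alphabet")
  }
  if (format == "fasta") {
    x <- tryCatch(Biostrings::readBStringSet(path, format = "fasta"),
                  error = function(e) {
                    stop("FASTA parse error in ", path, ": ",
                         conditionMessage(e))
                  })
    qual <- NULL
  } else {
    x <- tryCatch(
      Biostrings::readBStringSet(path, format = "fastq", with.qualities = TRUE),
      error = function(e) {
        stop("FASTQ parse error in ", path, ": ", conditionMessage(e))
      })
    qual <- as.character(S4Vectors::mcols(x)$qualities)
  }
  if (length(x) == 0L) stop("no records in ", path)
  nm <- names(x)
  id <- sub("\\s.*$", "", nm)
  desc <- ifelse(grepl("\\s", nm), sub("^\\S+\\s+", "", nm), "")
  seq_set(id, as.character(x), alphabet = alphabet, desc = desc,
          qual = qual, gapped = FALSE)
}

#' Write a sequence set as FASTA
#' @param x a [seq_set] (or alignment).
#' @param path output path.
#' @param width line-wrap width.
#' @return `path`, invisibly.
#' @export
write_sequences <- function(x, path, width = 70L) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(x$id)) {
    hdr <- if (nzchar(x$desc[i])) paste(x$id[i], x$desc[i]) else x$id[i]
    writeLines(paste0(">", hdr), con)
    s <- x$seq[i]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' Read a multiple alignment from gapped FASTA
#'
#' @param path FASTA path; all rows must be equal length and >= 2 rows.
#' @param alphabet `"dna"` or `"protein"`.
#' @return a `seq_aln` (subclass of [seq_set]) with attribute `n_columns`.
#' @export
read_alignment <- function(path, alphabet = c("dna", "protein")) {
  alphabet <- match.arg(alphabet)
  x <- Biostrings::readBStringSet(path, format = "fasta")
  nm <- sub("\\s.*$", "", names(x))
  as_alignment(seq_set(nm, as.character(x), alphabet = alphabet,
                       desc = ifelse(grepl("\\s", names(x)),
                                     sub("^\\S+\\s+", "", names(x)), ""),
                       gapped = TRUE))
}

#' Promote a gapped sequence set to an alignment
#' @param x a [seq_set] whose rows are equal length.
#' @return a `seq_aln`.
#' @export
as_alignment <- function(x) {
  if (length(x) < 2L) stop("alignment needs >=2 rows")
  w <- nchar(x$seq)
  if (length(unique(w)) != 1L) {
    off <- x$id[which(w != w[1L])[1L]]
    stop(sprintf("ragged alignment: row '%s' has length %d, expected %d",
                 off, nchar(x$seq[match(off, x$id)]), w[1L]))
  }
  structure(x, class = c("seq_aln", "seq_set"), n_columns = w[1L])
}

#' Number of alignment columns
#' @param aln a `seq_aln`.
#' @return integer column count.
#' @export
n_columns <- function(aln) attr(aln, "n_columns")

# alignment as a character matrix (rows x columns)
aln_matrix <- function(aln) {
  m <- do.call(rbind, strsplit(aln$seq, "", fixed = TRUE))
  rownames(m) <- aln$id
  m
}

#' Remove gaps from a residue string
#' @param seq residue string.
#' @return ungapped string.
#' @export
degap <- function(seq) gsub("-", "", seq, fixed = TRUE)

#' Read a phylogeny from Newick
#'
#' Missing branch lengths default to 0 with a warning; duplicate leaf
#' labels are rejected.
#'
#' @param path Newick file.
#' @return an [ape::phylo] tree.
#' @export
read_tree <- function(path) {
  tr <- tryCatch(ape::read.tree(path),
                 error = function(e) stop("Newick parse error in ", path, ": ",
                                          conditionMessage(e)))
  if (is.null(tr)) stop("Newick parse error in ", path)
  if (anyDuplicated(tr$tip.label)) {
    stop("duplicate leaf label: ",
         tr$tip.label[duplicated(tr$tip.label)][1L])
  }
  if (is.null(tr$edge.length)) {
    warning("tree has no branch lengths; all set to 0")
    tr$edge.length <- rep(0, nrow(tr$edge))
  } else if (anyNA(tr$edge.length)) {
    warning("missing branch lengths set to 0")
    tr$edge.length[is.na(tr$edge.length)] <- 0
  }
  if (any(tr$edge.length < 0)) stop("negative branch length in tree")
  tr
}

#' Write a phylogeny to Newick
#' @param tree an [ape::phylo].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_tree <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

validate_panel_table <- function(df) {
  if (!identical(sort(names(df)), sort(PANEL_COLUMNS))) {
    extra <- setdiff(names(df), PANEL_COLUMNS)
    missing <- setdiff(PANEL_COLUMNS, names(df))
    stop("panel table columns mismatch",
         if (length(extra)) paste0("; unknown: ", paste(extra, collapse = ", ")),
         if (length(missing)) paste0("; missing: ", paste(missing, collapse = ", ")))
  }
  df <- df[PANEL_COLUMNS]
  if (anyDuplicated(df$group_id)) {
    stop("duplicate group_id in panel table: ",
         df$group_id[duplicated(df$group_id)][1L])
  }
  for (col in c("fwd_seq", "rev_seq")) {
    for (i in seq_len(nrow(df))) {
      ch <- strsplit(toupper(df[[col]][i]), "", fixed = TRUE)[[1L]]
      bad <- which(!(ch %in% names(IUPAC_BITS)))
      if (length(bad)) {
        stop(sprintf("row %d (%s): invalid IUPAC character '%s' in %s",
                     i, df$group_id[i], ch[bad[1L]], col))
      }
    }
    df[[col]] <- toupper(df[[col]])
  }
  if (any(df$tm_min_c > df$tm_max_c)) {
    stop("tm_min_c > tm_max_c for group ",
         df$group_id[which(df$tm_min_c > df$tm_max_c)[1L]])
  }
  if (any(df$expected_len_bp <= 0)) stop("expected_len_bp must be > 0")
  df
}

#' Read a primer-panel table (TSV)
#'
#' Fixed header: `group_id fwd_seq rev_seq tm_min_c tm_max_c
#' expected_len_bp`.  Temperatures are degrees Celsius, lengths base pairs.
#'
#' @param path TSV file.
#' @return validated data.frame of class `panel_table`.
#' @export
read_panel <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          colClasses = c(group_id = "character"),
                          check.names = FALSE, stringsAsFactors = FALSE)
  df <- validate_panel_table(df)
  class(df) <- c("panel_table", "data.frame")
  df
}

#' Write a primer-panel table (TSV)
#'
#' Temperatures are formatted with two decimals so that write/read
#' round-trips are byte-identical.
#'
#' @param panel panel data.frame (validated).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_panel <- function(panel, path) {
  panel <- validate_panel_table(as.data.frame(panel))
  out <- data.frame(
    group_id = panel$group_id,
    fwd_seq = panel$fwd_seq,
    rev_seq = panel$rev_seq,
    tm_min_c = sprintf("%.2f", panel$tm_min_c),
    tm_max_c = sprintf("%.2f", panel$tm_max_c),
    expected_len_bp = as.integer(panel$expected_len_bp),
    stringsAsFactors = FALSE
  )
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}
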