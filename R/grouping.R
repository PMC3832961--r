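# Partitioning a gene-family phylogeny into primer-design groups.
#
# A group is a clade whose members are mutually close, either in patristic
# distance (substitutions/site summed along the tree path) or in percent
# nucleotide identity over the master alignment.  The partition is the set
# of maximal clades satisfying the closeness constraint, found by a
# deterministic post-order sweep; this is the unique minimal clade
# partition for a monotone constraint.

#' Patristic distance matrix of a tree
#'
#' @param tree an [ape::phylo] with branch lengths.
#' @return symmetric matrix (class `dist_matrix`, attribute
#'   `metric = "patristic"`), entry (i,j) the sum of branch lengths on the
#'   i-to-j path.
#' @export
patristic_distances <- function(tree) {
  if (is.null(tree$edge.length)) stop("tree has no branch lengths")
  d <- stats::cophenetic(tree)
  d <- d[tree$tip.label, tree$tip.label]
  structure(d, metric = "patristic", class = c("dist_matrix", class(d)))
}

#' Pairwise percent nucleotide identity of alignment rows
#'
#' Identity is computed over columns where both rows are non-gap:
#' `100 * matches / overlap`.  Pairs with zero overlapping columns get 0
#' with a warning.
#'
#' @param aln nucleotide `seq_aln`.
#' @return symmetric matrix (class `dist_matrix`, `metric = "identity"`),
#'   100 on the diagonal.
#' @export
identity_matrix <- function(aln) {
  if (aln$alphabet != "dna") stop("identity_matrix requires a dna alignment")
  m <- aln_matrix(aln)
  n <- nrow(m)
  out <- matrix(100, n, n, dimnames = list(rownames(m), rownames(m)))
  gap <- m == "-"
  warned <- FALSE
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      both <- !gap[i, ] & !gap[j, ]
      ov <- sum(both)
      if (ov == 0L) {
        if (!warned) {
          warning("row pair(s) with zero overlapping columns; identity set to 0")
          warned <- TRUE
        }
        pid <- 0
      } else {
        pid <- 100 * sum(m[i, both] == m[j, both]) / ov
      }
      out[i, j] <- out[j, i] <- pid
    }
  }
  structure(out, metric = "identity", class = c("dist_matrix", "matrix"))
}

# does the leaf set satisfy the within-group constraint?
group_ok <- function(labels, dist, max_within, identity) {
  if (length(labels) < 2L) return(TRUE)
  sub <- dist[labels, labels]
  vals <- sub[upper.tri(sub)]
  if (identity) min(vals) >= max_within else max(vals) <= max_within
}

#' Partition a tree into primer-design groups
#'
#' Finds the maximal clades whose members satisfy a closeness constraint:
#' maximum within-clade distance at most `max_within` for a patristic
#' matrix, or minimum within-clade identity at least `max_within` for an
#' identity matrix (the threshold is read in the metric's units).  The
#' sweep is post-order and deterministic: a node forms one group iff its
#' whole leaf set satisfies the constraint and its parent's does not.
#' Unrooted trees are midpoint-rooted first.
#'
#' Groups smaller than `min_group_size` are merged into the smallest
#' enclosing ancestral clade that still satisfies the constraint when such
#' a clade exists; otherwise they are kept and flagged (`flagged = TRUE`).
#'
#' @param tree an [ape::phylo].
#' @param dist a `dist_matrix` from [patristic_distances] or
#'   [identity_matrix]; labels must equal the tree's leaves.
#' @param max_within closeness threshold (substitutions/site, or percent
#'   identity for an identity matrix).  Default 2.0 substitutions/site.
#' @param min_group_size minimum members per group (default 1).
#' @return list of `primer_group` objects: `group_id` (integer, in tree
#'   order), `member_ids`, `flagged`.
#' @export
partition_tree <- function(tree, dist, max_within = 2.0, min_group_size = 1L) {
  if (max_within <= 0) stop("max_within threshold must be > 0")
  identity <- identical(attr(dist, "metric"), "identity")
  if (!setequal(rownames(dist), tree$tip.label) ||
      !setequal(colnames(dist), tree$tip.label)) {
    stop("distance-matrix labels do not match tree leaves")
  }
  if (!ape::is.rooted(tree)) tree <- phangorn::midpoint(tree)
  tree <- stats::reorder(tree, "postorder")
  ntip <- length(tree$tip.label)
  nnode <- ntip + tree$Nnode
  kids <- vector("list", nnode)
  for (e in seq_len(nrow(tree$edge))) {
    p <- tree$edge[e, 1L]
    kids[[p]] <- c(kids[[p]], tree$edge[e, 2L])
  }
  leafset <- vector("list", nnode)
  for (i in seq_len(ntip)) leafset[[i]] <- tree$tip.label[i]
  ok <- logical(nnode)
  post <- unique(tree$edge[, 2L])            # postorder child nodes
  post <- c(post[post > ntip], ntip + 1L)    # internal nodes then root
  for (i in seq_len(ntip)) ok[i] <- TRUE
  for (v in post) {
    leafset[[v]] <- unlist(lapply(kids[[v]], function(k) leafset[[k]]))
    ok[v] <- group_ok(leafset[[v]], dist, max_within, identity)
  }
  # maximal satisfying clades: descend from the root, stop at ok nodes
  groups <- list()
  descend <- function(v) {
    if (ok[v]) {
      groups[[length(groups) + 1L]] <<- leafset[[v]]
    } else {
      for (k in kids[[v]]) descend(k)
    }
  }
  descend(ntip + 1L)
  # ancestor chain per group for the min-size merge: map each group to the
  # node it came from, then walk up looking for a satisfying ancestor
  flagged <- rep(FALSE, length(groups))
  if (min_group_size > 1L) {
    parent <- integer(nnode)
    for (e in seq_len(nrow(tree$edge))) parent[tree$edge[e, 2L]] <- tree$edge[e, 1L]
    repeat {
      small <- which(lengths(groups) < min_group_size & !flagged)
      if (length(small) == 0L) break
      g <- small[1L]
      # smallest enclosing clade (walk up from the group's node) whose full
      # leaf set satisfies the constraint
      node <- find_node(groups[[g]], leafset, ntip)
      merged <- FALSE
      v <- node
      while (v != ntip + 1L && parent[v] != 0L) {
        v <- parent[v]
        if (group_ok(leafset[[v]], dist, max_within, identity)) {
          absorb <- leafset[[v]]
          drop <- vapply(groups, function(x) all(x %in% absorb), logical(1L))
          groups <- c(groups[!drop], list(absorb))
          flagged <- c(flagged[!drop], FALSE)
          merged <- TRUE
          break
        }
      }
      if (!merged) flagged[g] <- TRUE
    }
  }
  # order groups by tree order of their first leaf; assign ids
  first_leaf <- vapply(groups, function(g) min(match(g, tree$tip.label)),
                       integer(1L))
  o <- order(first_leaf)
  groups <- groups[o]
  flagged <- flagged[o]
  check_partition(groups, tree$tip.label)
  lapply(seq_along(groups), function(i) {
    structure(list(group_id = i,
                   member_ids = groups[[i]][order(match(groups[[i]], tree$tip.label))],
                   flagged = flagged[i]),
              class = "primer_group")
  })
}

find_node <- function(leaves, leafset, ntip) {
  for (v in seq_along(leafset)) {
    if (!is.null(leafset[[v]]) && setequal(leafset[[v]], leaves)) return(v)
  }
  stop("internal error: group is not a clade")
}

check_partition <- function(groups, leaves) {
  all_members <- unlist(groups)
  if (anyDuplicated(all_members) || !setequal(all_members, leaves)) {
    stop("internal error: groups do not partition the leaf set")
  }
  invisible(TRUE)
}

#' @export
print.primer_group <- function(x, ...) {
  cat(sprintf("<primer_group %d> %d member(s)%s: %s\n", x$group_id,
              length(x$member_ids), if (isTRUE(x$flagged)) " [flagged]" else "",
              paste(utils::head(x$member_ids, 8L), collapse = ", ")))
  invisible(x)
}

#' Restrict the master alignment to one group
#'
#' Rows are subset to the group members (kept in the supplied member
#' order, which [partition_tree] sets to tree order) and columns that are
#' gaps in every retained row are removed.
#'
#' @param aln master `seq_aln`.
#' @param group a `primer_group` (or character vector of member ids).
#' @return `seq_aln` for the group.
#' @export
extract_group_alignment <- function(aln, group) {
  members <- if (inherits(group, "primer_group")) group$member_ids else group
  missing <- setdiff(members, aln$id)
  if (length(missing)) {
    stop("group member(s) absent from alignment: ",
         paste(missing, collapse = ", "))
  }
  sub <- aln[members]
  m <- do.call(rbind, strsplit(sub$seq, "", fixed = TRUE))
  keep <- colSums(m != "-") > 0L
  sub$seq <- apply(m[, keep, drop = FALSE], 1L, paste, collapse = "")
  if (length(members) < 2L) {
    # single-member groups degrade to a plain seq_set with one row kept
    # gapless-consistent; still return an alignment-like object
    return(structure(sub, class = c("seq_aln", "seq_set"),
                     n_columns = nchar(sub$seq[1L])))
  }
  as_alignment(sub)
}
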