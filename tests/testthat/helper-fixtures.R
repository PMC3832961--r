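# Shared fixture builders (all generated in code, seeded).

write_tmp_fasta <- function(ids, seqs) {
  path <- tempfile(fileext = ".fasta")
  writeLines(as.vector(rbind(paste0(">", ids), seqs)), path)
  path
}

# two well-separated clades joined by a long internal branch, each clade a
# coherent simulated family: gives a guaranteed two-group structure
make_two_group_family <- function(seed, n_each = 6L, divergence = 0.08) {
  f1 <- simulate_family(family_spec(n_taxa = n_each,
                                    mean_divergence = divergence,
                                    seed = seed))
  f2 <- simulate_family(family_spec(n_taxa = n_each,
                                    mean_divergence = divergence,
                                    seed = seed + 1000L))
  f2$tree$tip.label <- sub("member_", "memberB_", f2$tree$tip.label)
  f2$sequences$id <- sub("member_", "memberB_", f2$sequences$id)
  s1 <- sub(";$", "", ape::write.tree(f1$tree))
  s2 <- sub(";$", "", ape::write.tree(f2$tree))
  tree <- ape::read.tree(text = paste0("(", s1, ":2.5,", s2, ":2.5);"))
  ids <- c(f1$sequences$id, f2$sequences$id)
  seqs <- c(f1$sequences$seq, f2$sequences$seq)
  sequences <- seq_set(ids, seqs, alphabet = "dna")
  membership <- stats::setNames(rep(c("1", "2"), each = n_each), ids)
  list(tree = tree, alignment = as_alignment(sequences),
       sequences = sequences, membership = membership)
}
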