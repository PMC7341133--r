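# Independent oracles and generators used across the suite. Nothing here
# calls the code paths under test: the parsimony oracle enumerates all
# internal-state assignments by brute force.

# Minimum number of state changes over all assignments of internal states,
# leaves fixed at `tip_states` (named by tip label).
bf_parsimony_min <- function(tree, tip_states, alphabet) {
  ntip <- length(tree$tip.label)
  nnode <- tree$Nnode
  grid <- expand.grid(rep(list(alphabet), nnode), stringsAsFactors = FALSE)
  edges <- tree$edge
  tip_vec <- unname(tip_states[tree$tip.label])
  best <- Inf
  for (g in seq_len(nrow(grid))) {
    states <- c(tip_vec, as.character(grid[g, ]))
    cost <- sum(states[edges[, 1]] != states[edges[, 2]])
    if (cost < best) best <- cost
  }
  best
}

# Random rooted tree with n leaves; internal edges are collapsed with
# probability p_collapse to produce multifurcations.
random_test_tree <- function(n_leaves, p_collapse = 0.3) {
  tr <- ape::rtree(n_leaves)
  internal <- tr$edge[, 2] > n_leaves
  tr$edge.length[internal] <- ifelse(stats::runif(sum(internal)) < p_collapse,
                                     0, 1)
  tr$edge.length[!internal] <- 1
  tr <- ape::di2multi(tr, tol = 1e-8)
  label_internal_nodes(tr)
}

# map internal node labels to the sorted tip sets they subtend
clade_tip_map <- function(tree) {
  ntip <- length(tree$tip.label)
  out <- lapply(seq_len(tree$Nnode), function(i) {
    sort(ape::extract.clade(tree, ntip + i)$tip.label)
  })
  names(out) <- tree$node.label
  out
}

# random amino-acid-like sequence records for round-trip tests
random_records <- function(n, alphabet = c("A", "C", "D", "E", "G", "-"),
                           min_len = 5, max_len = 40) {
  seqs <- vapply(seq_len(n), function(i) {
    paste(sample(alphabet, sample(min_len:max_len, 1), replace = TRUE),
          collapse = "")
  }, character(1))
  names(seqs) <- paste0("rec", seq_len(n))
  seqs
}

aa20 <- sort(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]])

# tiny in-memory PDB writer for structure tests
toy_pdb <- function(atoms, path) {
  lines <- vapply(seq_len(nrow(atoms)), function(i) {
    a <- atoms[i, ]
    sprintf("ATOM  %5d  %-3s%1s%3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
            i, a$atom, ifelse(is.na(a$altloc), " ", a$altloc), a$resname,
            a$chain, a$resseq, a$x, a$y, a$z,
            ifelse(is.na(a$occ), 1, a$occ), 0, a$element)
  }, character(1))
  writeLines(c(lines, "END"), path)
  path
}
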