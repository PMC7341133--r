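# The 20-residue state alphabet, sorted; "X" is the internal missing symbol.
.AA20 <- sort(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]])
.MISSING_CHARS <- c("-", ".", "X", "?", "*")

normalize_missing <- function(chars) {
  chars[chars %in% .MISSING_CHARS] <- "X"
  chars
}

#' Ancestral reconstruction by small parsimony
#'
#' Assigns a residue state to every internal node for every alignment column
#' so that the number of state changes on the tree is minimal (small
#' parsimony). The bottom-up pass uses Hartigan's generalisation of the
#' Fitch algorithm, which is exactly minimal on multifurcating as well as
#' binary trees; on binary trees it reduces to the classic Fitch
#' intersection/union rule, with the per-column score equal to the number of
#' union events.
#'
#' Missing leaf states (gap, `X`, `?`, `*`) are treated as the full state
#' set during the bottom-up pass, so they never constrain the reconstruction
#' or contribute to the score; an internal node all of whose descendant
#' leaves are missing in a column is assigned the missing symbol `X` there.
#' The top-down pass is deterministic: a node inherits its parent's state
#' whenever that state is among its optimal candidates, and otherwise (and
#' at the root) takes the alphabetically smallest candidate. Branch lengths
#' are ignored.
#'
#' @param tree A rooted `phylo` whose leaf labels are a subset of the
#'   alignment row ids (see [root_on_edge()]).
#' @param aln An alignment from [as_msa()] (amino-acid alphabet).
#' @param chunk Number of columns processed per block (memory knob).
#' @return An object of class `ancestral_assignment`: a list with `tree`,
#'   `states` (character matrix, one row per node — leaves first, then
#'   internal nodes — one column per alignment column) and `score` (integer
#'   per-column parsimony score).
#' @export
reconstruct <- function(tree, aln, chunk = 512L) {
  # a basal polytomy is treated as a rooted multifurcation at the ape root
  # node; use root_on_edge() first when an outgroup rooting is intended
  tree <- label_internal_nodes(tree)
  aln <- as_msa(aln)
  ntip <- length(tree$tip.label)
  nnode <- tree$Nnode
  n_all <- ntip + nnode
  absent <- setdiff(tree$tip.label, rownames(aln))
  if (length(absent) > 0L) {
    stop("leaf/leaves without an alignment row: ",
         paste(absent, collapse = ", "), call. = FALSE)
  }
  ncolumns <- ncol(aln)
  nstate <- length(.AA20)
  leaf_chars <- normalize_missing(unclass(aln)[tree$tip.label, , drop = FALSE])
  bad <- setdiff(unique(as.vector(leaf_chars)), c(.AA20, "X"))
  if (length(bad) > 0L) {
    stop("non amino-acid state(s) in alignment: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }

  po <- stats::reorder(tree, "postorder")$edge
  pre <- stats::reorder(tree, "cladewise")$edge
  root <- root_index(tree)
  children <- split(po[, 2], po[, 1])

  states <- matrix("X", n_all, ncolumns,
                   dimnames = list(node_labels(tree), NULL))
  score <- integer(ncolumns)

  for (lo in seq(1L, ncolumns, by = chunk)) {
    hi <- min(lo + chunk - 1L, ncolumns)
    w <- hi - lo + 1L
    cols <- lo:hi
    # candidate-set array: S[state, column, node]
    S <- array(FALSE, c(nstate, w, n_all))
    allmiss <- matrix(FALSE, n_all, w)
    for (i in seq_len(ntip)) {
      ch <- leaf_chars[i, cols]
      miss <- ch == "X"
      m <- matrix(FALSE, nstate, w)
      m[cbind(match(ch[!miss], .AA20), which(!miss))] <- TRUE
      m[, miss] <- TRUE  # missing leaf = uninformative, full state set
      S[, , i] <- m
      allmiss[i, ] <- miss
    }
    sc <- integer(w)
    internal_po <- unique(po[, 1])  # children always precede parents
    for (v in internal_po) {
      kids <- children[[as.character(v)]]
      cnt <- matrix(0L, nstate, w)
      for (k in kids) cnt <- cnt + S[, , k]
      m <- cnt[1, ]
      for (s in 2:nstate) m <- pmax(m, cnt[s, ])
      S[, , v] <- cnt == matrix(m, nstate, w, byrow = TRUE)
      allmiss[v, ] <- apply(allmiss[kids, , drop = FALSE], 2L, all)
      sc <- sc + (length(kids) - m)
    }
    # score never charges all-missing subtrees: their m equals the child count
    score[cols] <- sc

    # top-down resolution
    first_cand <- function(v) .AA20[apply(S[, , v, drop = FALSE], 2L, which.max)]
    rs <- first_cand(root)
    rs[allmiss[root, ]] <- "X"
    states[root, cols] <- rs
    for (e in seq_len(nrow(pre))) {
      p <- pre[e, 1]; v <- pre[e, 2]
      if (v <= ntip) {
        states[v, cols] <- leaf_chars[v, cols]
        next
      }
      ps <- states[p, cols]
      keep <- ps != "X" &
        S[cbind(match(ps, .AA20, nomatch = 1L), seq_len(w),
                rep(v, w))] & !is.na(match(ps, .AA20))
      st <- first_cand(v)
      st[keep] <- ps[keep]
      st[allmiss[v, ]] <- "X"
      states[v, cols] <- st
    }
  }
  structure(list(tree = tree, states = states, score = score),
            class = "ancestral_assignment")
}

#' @export
print.ancestral_assignment <- function(x, ...) {
  ntip <- length(x$tree$tip.label)
  cat("<ancestral_assignment> ", ntip, " leaves, ", x$tree$Nnode,
      " internal nodes, ", ncol(x$states), " columns; total parsimony score ",
      sum(x$score), "\n", sep = "")
  invisible(x)
}

#' Serialize an ancestral assignment
#'
#' Writes the reconstruction both as a long TSV (`node`, `column`, `state`)
#' and as a FASTA of ancestral sequences (one record per internal node).
#'
#' @param assignment An `ancestral_assignment`.
#' @param tsv_path,fasta_path Output paths; either may be `NULL` to skip.
#' @return Invisibly, a list of the written paths.
#' @export
write_assignment <- function(assignment, tsv_path = NULL, fasta_path = NULL) {
  st <- assignment$states
  if (!is.null(tsv_path)) {
    long <- data.frame(node = rep(rownames(st), ncol(st)),
                       column = rep(seq_len(ncol(st)), each = nrow(st)),
                       state = as.vector(st), stringsAsFactors = FALSE)
    utils::write.table(long, tsv_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  if (!is.null(fasta_path)) {
    internal <- assignment$tree$node.label
    seqs <- apply(st[internal, , drop = FALSE], 1L, paste, collapse = "")
    write_fasta(seqs, fasta_path)
  }
  invisible(list(tsv = tsv_path, fasta = fasta_path))
}
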