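#' Read a Newick tree
#'
#' Reads a Newick file via \pkg{ape} and ensures every node carries a unique
#' label: unlabeled internal nodes are given deterministic synthetic labels
#' `N1, N2, ...` in preorder (root first).
#'
#' @param path Path to a Newick file (with or without branch lengths and
#'   internal labels).
#' @return An \pkg{ape} `phylo` object with complete `node.label`.
#' @export
read_newick <- function(path) {
  tr <- tryCatch(ape::read.tree(path),
                 error = function(e) stop("Newick parse failure in '", path,
                                          "': ", conditionMessage(e),
                                          call. = FALSE))
  if (is.null(tr)) stop("Newick parse failure in '", path, "'", call. = FALSE)
  if (inherits(tr, "multiPhylo")) tr <- tr[[1]]
  dup <- unique(tr$tip.label[duplicated(tr$tip.label)])
  if (length(dup) > 0L) {
    stop("duplicate leaf label(s): ", paste(dup, collapse = ", "),
         call. = FALSE)
  }
  label_internal_nodes(tr)
}

#' Write a tree to a Newick file
#'
#' @param tree A `phylo` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' Assign deterministic labels to unlabeled internal nodes
#'
#' Internal nodes with no label (or an empty/NA label) are named
#' `N1, N2, ...` in preorder; existing labels are kept. Generated names skip
#' any label already present so that all node labels end up unique.
#'
#' @param tree A `phylo` object.
#' @return The tree with complete, unique `node.label`.
#' @export
label_internal_nodes <- function(tree) {
  ntip <- length(tree$tip.label)
  nnode <- tree$Nnode
  lab <- tree$node.label
  if (is.null(lab)) lab <- rep("", nnode)
  lab[is.na(lab)] <- ""
  ord <- stats::reorder(tree, "cladewise")$edge
  root <- setdiff(ord[, 1], ord[, 2])[1]
  pre_internal <- unique(c(root, ord[, 2][ord[, 2] > ntip]))
  taken <- c(tree$tip.label, lab[nzchar(lab)])
  counter <- 0L
  for (node in pre_internal) {
    i <- node - ntip
    if (!nzchar(lab[i])) {
      repeat {
        counter <- counter + 1L
        cand <- paste0("N", counter)
        if (!cand %in% taken) break
      }
      lab[i] <- cand
      taken <- c(taken, cand)
    }
  }
  if (anyDuplicated(lab)) {
    stop("internal node labels are not unique: ",
         paste(unique(lab[duplicated(lab)]), collapse = ", "), call. = FALSE)
  }
  tree$node.label <- lab
  tree
}

# All node labels in ape index order (tips 1..ntip, then internals).
node_labels <- function(tree) c(tree$tip.label, tree$node.label)

# ape index of the root node.
root_index <- function(tree) {
  ntip <- length(tree$tip.label)
  setdiff(unique(tree$edge[, 1]), tree$edge[, 2])[1]
}

#' Root a tree on the edge subtending an outgroup
#'
#' Places the root on the edge leading to `outgroup_label`, which may name a
#' leaf or an internal (clade-defining) node. If the tree is already rooted
#' with that outgroup as a child of the root, it is returned unchanged.
#'
#' @param tree A `phylo` object (rooted or unrooted).
#' @param outgroup_label A leaf label or internal node label present in the
#'   tree.
#' @return A rooted `phylo` with the outgroup as one child of the root and
#'   complete internal labels.
#' @export
root_on_edge <- function(tree, outgroup_label) {
  tree <- label_internal_nodes(tree)
  ntip <- length(tree$tip.label)
  labs <- node_labels(tree)
  if (!outgroup_label %in% labs) {
    stop("label '", outgroup_label, "' not found in the tree", call. = FALSE)
  }
  og_tips <- if (outgroup_label %in% tree$tip.label) {
    outgroup_label
  } else {
    node <- ntip + match(outgroup_label, tree$node.label)
    ape::extract.clade(tree, node)$tip.label
  }
  if (ape::is.rooted(tree)) {
    root <- root_index(tree)
    kids <- tree$edge[tree$edge[, 1] == root, 2]
    for (k in kids) {
      kid_tips <- if (k <= ntip) tree$tip.label[k] else {
        ape::extract.clade(tree, k)$tip.label
      }
      if (setequal(kid_tips, og_tips)) return(tree)  # already rooted there
    }
  }
  rooted <- ape::root(ape::unroot(tree), outgroup = og_tips,
                      resolve.root = TRUE)
  rooted$node.label[!nzchar(rooted$node.label) | is.na(rooted$node.label)] <- ""
  label_internal_nodes(rooted)
}
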