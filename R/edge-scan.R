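#' Build the per-edge binary substitution table
#'
#' For every tree edge and every alignment column, records an indicator that
#' is 1 exactly when the ancestral (parent) and descendant (child) states
#' differ and both are observed amino acids. Transitions to or from the
#' missing symbol are not substitutions. Edges are listed in preorder and
#' identified as `parent->child` by node label.
#'
#' @param assignment An `ancestral_assignment` from [reconstruct()].
#' @return An object of class `edge_table`: a list with `edges` (data.frame
#'   `parent`, `child`, `terminal`) and `indicator` (0/1 integer matrix,
#'   rows = edges, columns = alignment columns).
#' @export
build_edge_table <- function(assignment) {
  stopifnot(inherits(assignment, "ancestral_assignment"))
  tree <- assignment$tree
  ntip <- length(tree$tip.label)
  labs <- node_labels(tree)
  pre <- stats::reorder(tree, "cladewise")$edge
  st <- assignment$states
  p_states <- st[pre[, 1], , drop = FALSE]
  c_states <- st[pre[, 2], , drop = FALSE]
  ind <- (p_states != c_states) & (p_states != "X") & (c_states != "X")
  mode(ind) <- "integer"
  edges <- data.frame(parent = labs[pre[, 1]], child = labs[pre[, 2]],
                      terminal = pre[, 2] <= ntip, stringsAsFactors = FALSE)
  rownames(ind) <- paste0(edges$parent, "->", edges$child)
  colnames(ind) <- NULL
  out <- structure(list(edges = edges, indicator = ind), class = "edge_table")
  # double-counting identity is structural; assert it on every build
  stopifnot(sum(rowSums(ind)) == sum(colSums(ind)))
  out
}

#' @export
print.edge_table <- function(x, ...) {
  cat("<edge_table> ", nrow(x$indicator), " edges x ", ncol(x$indicator),
      " columns; ", sum(x$indicator), " substitutions (",
      sum(x$indicator[!x$edges$terminal, , drop = FALSE]),
      " on internal edges)\n", sep = "")
  invisible(x)
}

#' Per-edge substitution totals
#'
#' Sums the substitution indicators across all columns for each edge and
#' ranks edges by total, descending (ties broken by edge label). By default
#' only internal edges enter the ranking, matching a survey of
#' lineage-defining changes; terminal edges can be included.
#'
#' @param table An `edge_table`.
#' @param include_terminal Keep edges leading to leaves (default `FALSE`).
#' @return A data.frame `parent`, `child`, `terminal`, `total`, sorted by
#'   decreasing total.
#' @export
edge_totals <- function(table, include_terminal = FALSE) {
  stopifnot(inherits(table, "edge_table"))
  tot <- rowSums(table$indicator)
  out <- cbind(table$edges, total = as.integer(tot))
  if (!include_terminal) out <- out[!out$terminal, , drop = FALSE]
  lab <- paste0(out$parent, "->", out$child)
  out <- out[order(-out$total, lab), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Per-column substitution counts
#'
#' Number of times each alignment position changed anywhere on the tree
#' (the column sums of the indicator matrix).
#'
#' @param table An `edge_table`.
#' @return Integer vector, one count per alignment column.
#' @export
position_change_counts <- function(table) {
  stopifnot(inherits(table, "edge_table"))
  as.integer(colSums(table$indicator))
}

# index of the edge whose child has the given label
.edge_index <- function(table, focal_child) {
  i <- which(table$edges$child == focal_child)
  if (length(i) == 0L) {
    stop("'", focal_child, "' has no parent edge (is it the root?)",
         call. = FALSE)
  }
  i[1]
}

#' Report ancestral and descendant states on a focal edge
#'
#' Lists every column substituted on the edge leading into `focal_child`
#' together with the reconstructed ancestral and descendant residues — the
#' per-lineage change list from which candidate positions are drawn.
#'
#' @param assignment An `ancestral_assignment`.
#' @param table The matching `edge_table`.
#' @param focal_child Node label of the descendant end of the focal edge
#'   (e.g. the ancestor of a clade of interest).
#' @return A data.frame of class `edge_report` with columns `column`,
#'   `ancestral`, `descendant` (and `ref_position` once annotated); the edge
#'   is stored in attributes `parent`/`child`.
#' @export
focal_edge_report <- function(assignment, table, focal_child) {
  stopifnot(inherits(assignment, "ancestral_assignment"),
            inherits(table, "edge_table"))
  i <- .edge_index(table, focal_child)
  parent <- table$edges$parent[i]
  cols <- which(table$indicator[i, ] == 1L)
  rep <- data.frame(column = cols,
                    ancestral = assignment$states[parent, cols],
                    descendant = assignment$states[focal_child, cols],
                    stringsAsFactors = FALSE)
  rownames(rep) <- NULL
  structure(rep, class = c("edge_report", "data.frame"),
            parent = parent, child = focal_child)
}

#' Rank focal-edge columns by tree-wide change count
#'
#' Among the columns substituted on the focal edge, orders positions by how
#' often they changed anywhere in the tree (ascending). The top row is the
#' most conserved position altered on that lineage — the selection rule that
#' singles out a uniquely-substituted candidate site.
#'
#' @inheritParams focal_edge_report
#' @return A data.frame `column`, `tree_count`, ascending by count then
#'   column.
#' @export
rank_focal_columns <- function(table, focal_child) {
  stopifnot(inherits(table, "edge_table"))
  i <- .edge_index(table, focal_child)
  cols <- which(table$indicator[i, ] == 1L)
  counts <- position_change_counts(table)[cols]
  out <- data.frame(column = cols, tree_count = counts)
  out <- out[order(out$tree_count, out$column), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Observed character sets at positions of interest
#'
#' For each requested column, the set of residues observed at any node of
#' the tree — leaves and reconstructed internal nodes alike — excluding the
#' missing symbol.
#'
#' @param assignment An `ancestral_assignment`.
#' @param columns Integer vector of alignment columns.
#' @return A named list (by column) of sorted character vectors.
#' @export
position_character_sets <- function(assignment, columns) {
  stopifnot(inherits(assignment, "ancestral_assignment"))
  ncolumns <- ncol(assignment$states)
  if (any(columns < 1L | columns > ncolumns)) {
    stop("column out of range 1..", ncolumns, call. = FALSE)
  }
  out <- lapply(columns, function(j) {
    sort(setdiff(unique(assignment$states[, j]), "X"))
  })
  names(out) <- as.character(columns)
  out
}

#' Write an edge table to TSV files
#'
#' @param table An `edge_table`.
#' @param wide_path Dense TSV (rows = edges, cells 0/1); `NULL` to skip.
#' @param sparse_path Sparse triples TSV (`parent`, `child`, `column`);
#'   `NULL` to skip.
#' @return Invisibly, the written paths.
#' @export
write_edge_table <- function(table, wide_path = NULL, sparse_path = NULL) {
  stopifnot(inherits(table, "edge_table"))
  if (!is.null(wide_path)) {
    wide <- cbind(table$edges[, c("parent", "child")],
                  as.data.frame(table$indicator))
    names(wide) <- c("parent", "child", paste0("col", seq_len(ncol(table$indicator))))
    utils::write.table(wide, wide_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  if (!is.null(sparse_path)) {
    hits <- which(table$indicator == 1L, arr.ind = TRUE)
    sp <- data.frame(parent = table$edges$parent[hits[, 1]],
                     child = table$edges$child[hits[, 1]],
                     column = hits[, 2], stringsAsFactors = FALSE)
    sp <- sp[order(sp$column, sp$parent, sp$child), , drop = FALSE]
    utils::write.table(sp, sparse_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(list(wide = wide_path, sparse = sparse_path))
}
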