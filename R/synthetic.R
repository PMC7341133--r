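# Run code under a fixed RNG seed, restoring the caller's RNG state after.
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# random rooted binary topology over atomic newick units
.rand_topology <- function(units) {
  n <- length(units)
  if (n == 1L) return(units)
  if (n == 2L) return(paste0("(", units[1], ",", units[2], ")"))
  k <- sample.int(n - 1L, 1L)
  pick <- sort(sample.int(n, k))
  paste0("(", .rand_topology(units[pick]), ",",
         .rand_topology(units[-pick]), ")")
}

#' Simulate a clade-structured rooted tree
#'
#' Generates a random rooted binary tree with a designated outgroup leaf as
#' one child of the root and any number of labeled monophyletic clades
#' inside the ingroup — the scaffold on which substitutions are planted
#' (e.g. a small focal clade inside a large ingroup, mirroring a compact
#' family nested in a big phylogeny). The most recent common ancestor of
#' each clade is labeled with the clade's name, so the edge into a clade can
#' be addressed directly (e.g. `focal_child = "focal"`).
#'
#' @param n_leaves Total number of leaves including the outgroup (>= 3).
#' @param clade_spec Named integer vector of clade sizes, e.g.
#'   `c(focal = 15)`. Clade leaves are named `<clade>_1 ...`; remaining
#'   ingroup leaves `t1, t2, ...`.
#' @param seed RNG seed (mandatory; the same seed reproduces the identical
#'   Newick string).
#' @param outgroup Label of the outgroup leaf.
#' @return A rooted `phylo` with complete node labels.
#' @export
simulate_tree <- function(n_leaves, clade_spec = c(focal = 3), seed,
                          outgroup = "outgroup") {
  stopifnot(n_leaves >= 3)
  sizes <- as.integer(clade_spec)
  names(sizes) <- names(clade_spec)
  if (any(sizes < 1L)) stop("clade sizes must be >= 1", call. = FALSE)
  n_bg <- n_leaves - 1L - sum(sizes)
  if (n_bg < 0L) {
    stop("clade sizes plus the outgroup exceed n_leaves", call. = FALSE)
  }
  with_seed(seed, {
    units <- if (n_bg > 0L) paste0("t", seq_len(n_bg)) else character(0)
    for (cn in names(sizes)) {
      tips <- paste0(cn, "_", seq_len(sizes[[cn]]))
      sub <- if (length(tips) == 1L) tips else {
        paste0(.rand_topology(sample(tips)), cn)  # MRCA labeled by clade name
      }
      units <- c(units, sub)
    }
    ingroup <- .rand_topology(sample(units))
    nwk <- paste0("(", outgroup, ",", ingroup, ");")
    tr <- ape::read.tree(text = nwk)
    label_internal_nodes(tr)
  })
}

#' Evolve an alignment on a tree with planted substitutions
#'
#' Draws a uniform random root sequence over the 20 amino acids and evolves
#' it down the tree: on every edge each column receives a Poisson-distributed
#' number of background substitutions (target residue uniform over the other
#' 19), after which any planted events assigned to that edge are applied.
#' Every applied change is recorded as ground truth.
#'
#' In homoplasy-free mode, background events are rejected when they would
#' touch a planted column, reuse a column already substituted elsewhere in
#' the tree, fall on an edge that carries planted events, or fall on one of
#' the two edges incident to the root (a change there cannot be oriented by
#' any reconstruction method, so ground truth would not be identifiable) —
#' so the realised event list has at most one event per column, the focal
#' edge's substitution set is exactly its planted list, and parsimony
#' reconstruction recovers every event at its true (edge, column).
#'
#' @param tree A rooted `phylo` with complete labels (see
#'   [simulate_tree()]). Branch lengths are ignored; the rate is per edge.
#' @param n_columns Alignment length.
#' @param background_rate Expected substitutions per column per edge.
#' @param planted_events `NULL` or a data.frame with columns `child` (node
#'   label of the edge's descendant end), `column`, `from`, `to`. The root
#'   state of each planted column is set to `from`; a `from` that conflicts
#'   with the state reached at the edge's parent raises an error.
#' @param seed RNG seed (mandatory).
#' @param homoplasy_free Reject background events as described above.
#' @return A list with `aln` (leaf alignment, [as_msa()] matrix) and `truth`
#'   (class `simulation_truth`: `tree`, `states` for every node, `events`
#'   data.frame with `parent`, `child`, `column`, `from`, `to`, `planted`,
#'   and `seed`).
#' @export
evolve_alignment <- function(tree, n_columns, background_rate = 0.01,
                             planted_events = NULL, seed,
                             homoplasy_free = FALSE) {
  stopifnot(ape::is.rooted(tree), n_columns >= 1, background_rate >= 0)
  tree <- label_internal_nodes(tree)
  labs <- node_labels(tree)
  ntip <- length(tree$tip.label)
  n_all <- ntip + tree$Nnode
  pre <- stats::reorder(tree, "cladewise")$edge
  root <- root_index(tree)

  pe <- planted_events
  if (!is.null(pe) && nrow(pe) > 0L) {
    stopifnot(all(c("child", "column", "from", "to") %in% names(pe)))
    bad <- setdiff(pe$child, labs)
    if (length(bad) > 0L) {
      stop("planted event child label(s) not in tree: ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
    if (any(pe$column < 1L | pe$column > n_columns)) {
      stop("planted column out of range", call. = FALSE)
    }
    conflicting <- tapply(pe$from, pe$column, function(f) {
      length(unique(f[!is.na(f)])) > 1L
    })
    if (any(conflicting)) {
      stop("conflicting 'from' residues planted at the same column",
           call. = FALSE)
    }
  } else {
    pe <- data.frame(child = character(0), column = integer(0),
                     from = character(0), to = character(0))
  }

  with_seed(seed, {
    states <- matrix(NA_character_, n_all, n_columns,
                     dimnames = list(labs, NULL))
    rootseq <- sample(.AA20, n_columns, replace = TRUE)
    for (i in seq_len(nrow(pe))) {
      if (!is.na(pe$from[i])) rootseq[pe$column[i]] <- pe$from[i]
    }
    states[root, ] <- rootseq
    planted_cols <- unique(pe$column)
    planted_edges <- unique(pe$child)
    used_cols <- rep(FALSE, n_columns)
    used_cols[planted_cols] <- TRUE
    events <- list()

    for (e in seq_len(nrow(pre))) {
      p <- pre[e, 1]; v <- pre[e, 2]
      s <- states[p, ]
      child_label <- labs[v]
      mine <- which(pe$child == child_label)
      # background first, never on planted columns
      n_sub <- stats::rpois(n_columns, background_rate)
      n_sub[planted_cols] <- 0L
      if (homoplasy_free) {
        if (child_label %in% planted_edges || p == root) n_sub[] <- 0L
        n_sub[used_cols] <- 0L
        n_sub[n_sub > 1L] <- 1L
      }
      for (j in which(n_sub > 0L)) {
        for (rep_i in seq_len(n_sub[j])) {
          from <- s[j]
          to <- sample(setdiff(.AA20, from), 1L)
          s[j] <- to
          events[[length(events) + 1L]] <-
            data.frame(parent = labs[p], child = child_label, column = j,
                       from = from, to = to, planted = FALSE)
        }
        if (homoplasy_free) used_cols[j] <- TRUE
      }
      for (i in mine) {
        j <- pe$column[i]
        if (!is.na(pe$from[i]) && s[j] != pe$from[i]) {
          stop("planted event at column ", j, " on edge into '", child_label,
               "' expects ancestral '", pe$from[i], "' but found '", s[j],
               "'", call. = FALSE)
        }
        events[[length(events) + 1L]] <-
          data.frame(parent = labs[p], child = child_label, column = j,
                     from = s[j], to = pe$to[i], planted = TRUE)
        s[j] <- pe$to[i]
      }
      states[v, ] <- s
    }
    events <- if (length(events) > 0L) do.call(rbind, events) else {
      data.frame(parent = character(0), child = character(0),
                 column = integer(0), from = character(0), to = character(0),
                 planted = logical(0))
    }
    aln <- as_msa(states[seq_len(ntip), , drop = FALSE])
    truth <- structure(list(tree = tree, states = states, events = events,
                            seed = seed),
                       class = "simulation_truth")
    list(aln = aln, truth = truth)
  })
}

#' @export
print.simulation_truth <- function(x, ...) {
  cat("<simulation_truth> ", length(x$tree$tip.label), " leaves, ",
      ncol(x$states), " columns, ", nrow(x$events), " events (",
      sum(x$events$planted), " planted), seed ", x$seed, "\n", sep = "")
  invisible(x)
}

#' Simulate a complete lineage-scan scenario with a unique candidate column
#'
#' Convenience generator for the full edge-scan pipeline: a clade-structured
#' tree with a focal clade, and a homoplasy-free alignment carrying
#' `n_planted` substitutions on the edge into the focal clade. All planted
#' columns except the first also receive one planted event (with a distinct
#' derived residue) on a background terminal edge, so the first planted
#' column is the only focal-edge column substituted exactly once tree-wide —
#' the "most conserved position altered on the focal lineage" that
#' [rank_focal_columns()] should single out.
#'
#' @param n_leaves Total leaves including the outgroup.
#' @param focal_size Leaves in the focal clade (>= 2).
#' @param n_columns Alignment length.
#' @param n_planted Events planted on the focal edge.
#' @param background_rate Background substitution rate per column per edge.
#' @param seed RNG seed; sub-seeds `seed+1`, `seed+2` drive the alignment
#'   and the event draw.
#' @return A list: `tree`, `aln`, `truth`, `planted` (the planted-event
#'   data.frame), `focal_child` (`"focal"`) and `unique_column` (the
#'   uniquely-substituted planted column).
#' @export
simulate_scan_bundle <- function(n_leaves = 32, focal_size = 6,
                                 n_columns = 300, n_planted = 10,
                                 background_rate = 0.01, seed) {
  stopifnot(focal_size >= 2, n_planted >= 1, n_columns >= n_planted)
  n_bg <- n_leaves - 1L - focal_size
  if (n_bg < n_planted - 1L) {
    stop("need at least n_planted - 1 background leaves to pair planted ",
         "columns", call. = FALSE)
  }
  tree <- simulate_tree(n_leaves, c(focal = focal_size), seed = seed)
  # a background tip that is the focal clade's sister would make the paired
  # event's placement ambiguous under parsimony (the change could equally be
  # put on the edge above the focal clade), so exclude such tips
  ntip <- length(tree$tip.label)
  focal_node <- ntip + match("focal", tree$node.label)
  focal_parent <- tree$edge[tree$edge[, 2] == focal_node, 1]
  sibling_tips <- tree$tip.label[tree$edge[tree$edge[, 1] == focal_parent, 2]]
  candidates <- setdiff(grep("^t[0-9]+$", tree$tip.label, value = TRUE),
                        sibling_tips)
  if (length(candidates) < n_planted - 1L) {
    stop("not enough unambiguous background leaves for pairing", call. = FALSE)
  }
  planted <- with_seed(seed + 2L, {
    cols <- sort(sample.int(n_columns, n_planted))
    bg_tips <- sample(candidates, n_planted - 1L)
    rows <- lapply(seq_len(n_planted), function(i) {
      from <- sample(.AA20, 1L)
      to <- sample(setdiff(.AA20, from), 1L)
      ev <- data.frame(child = "focal", column = cols[i], from = from,
                       to = to, stringsAsFactors = FALSE)
      if (i > 1L) {
        to2 <- sample(setdiff(.AA20, c(from, to)), 1L)
        ev <- rbind(ev, data.frame(child = bg_tips[i - 1L], column = cols[i],
                                   from = from, to = to2,
                                   stringsAsFactors = FALSE))
      }
      ev
    })
    do.call(rbind, rows)
  })
  sim <- evolve_alignment(tree, n_columns, background_rate = background_rate,
                          planted_events = planted, seed = seed + 1L,
                          homoplasy_free = TRUE)
  list(tree = tree, aln = sim$aln, truth = sim$truth, planted = planted,
       focal_child = "focal",
       unique_column = planted$column[1])
}

#' Generate an annotated barcode panel with known fixation structure
#'
#' Builds per-clade nucleotide barcode fragments around a focal reference
#' position: each sample's protein is a window of the reference protein with
#' the focal residue set according to the requested clade spectrum, then
#' back-translated with random synonymous codons under the chosen genetic
#' code. A configurable fraction of each clade's samples is truncated just
#' before the focal position so that exactly the stated fraction covers it
#' — emulating partial barcode fragments. Ground truth records the planted
#' spectra, the coverage mask, and the spectrum observable among covering
#' samples.
#'
#' @param ref_protein The ungapped reference protein string.
#' @param focal_ref_pos 1-based focal position within `ref_protein`.
#' @param clade_spectra Named list: clade -> named integer vector of residue
#'   counts, e.g. `list(hummingbird = c(S = 914, A = 1))`.
#' @param coverage Fraction of samples per clade whose fragment covers the
#'   focal position (default 1).
#' @param code Genetic code for back-translation (object or id).
#' @param seed RNG seed (mandatory).
#' @param flank Integer pair: residues kept upstream/downstream of the focal
#'   position in a covering fragment.
#' @return A list with `barcodes` (named nucleotide vector), `annotations`
#'   (data.frame `id`, `clade`) and `truth` (list with `focal_ref_pos`,
#'   planted `spectra`, `observed_spectra` over covering samples, `covers`
#'   logical mask by sample id, `residues` by sample id, and `seed`).
#' @export
make_barcode_panel <- function(ref_protein, focal_ref_pos, clade_spectra,
                               coverage = 1, code = genetic_code(), seed,
                               flank = c(120L, 80L)) {
  stopifnot(length(ref_protein) == 1L, coverage >= 0, coverage <= 1,
            focal_ref_pos >= 1L, focal_ref_pos <= nchar(ref_protein))
  if (is.character(code) && !inherits(code, "genetic_code")) {
    code <- genetic_code(code)
  }
  len <- nchar(ref_protein)
  wstart <- max(1L, focal_ref_pos - flank[1])
  wend <- min(len, focal_ref_pos + flank[2])
  if (focal_ref_pos - wstart < 12L) {
    stop("focal position too close to the reference start for truncated ",
         "fragments", call. = FALSE)
  }
  with_seed(seed, {
    barcodes <- character(0)
    ids <- character(0)
    clades <- character(0)
    covers <- logical(0)
    residues <- character(0)
    for (cl in names(clade_spectra)) {
      spec <- clade_spectra[[cl]]
      res_vec <- rep(names(spec), times = as.integer(spec))
      n <- length(res_vec)
      res_vec <- sample(res_vec)  # shuffle residue order within the clade
      n_cov <- round(coverage * n)
      cov_mask <- rep(FALSE, n)
      if (n_cov > 0L) cov_mask[sample.int(n, n_cov)] <- TRUE
      for (k in seq_len(n)) {
        frag_end <- if (cov_mask[k]) wend else {
          focal_ref_pos - sample(3:10, 1L)
        }
        prot <- substr(ref_protein, wstart, frag_end)
        if (cov_mask[k]) {
          at <- focal_ref_pos - wstart + 1L
          substr(prot, at, at) <- res_vec[k]
        }
        id <- sprintf("%s_s%04d", cl, k)
        barcodes[id] <- back_translate(prot, code)
        ids <- c(ids, id)
        clades <- c(clades, cl)
        covers <- c(covers, cov_mask[k])
        residues <- c(residues, res_vec[k])
      }
    }
    names(covers) <- ids
    names(residues) <- ids
    observed <- lapply(names(clade_spectra), function(cl) {
      r <- residues[clades == cl & covers]
      sp <- table(r)
      sort(stats::setNames(as.integer(sp), names(sp)), decreasing = TRUE)
    })
    names(observed) <- names(clade_spectra)
    list(barcodes = barcodes,
         annotations = data.frame(id = ids, clade = clades,
                                  stringsAsFactors = FALSE),
         truth = list(focal_ref_pos = focal_ref_pos, spectra = clade_spectra,
                      observed_spectra = observed, covers = covers,
                      residues = residues, seed = seed))
  })
}
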