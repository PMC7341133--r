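#' Map alignment columns to reference residue numbering
#'
#' Builds the partial, strictly increasing map between alignment columns and
#' the ungapped 1-based residue numbering of a designated reference row —
#' the convention by which candidate positions are reported (e.g. "position
#' 153" in the numbering of a structurally characterised reference species).
#' The k-th non-gap column of the reference row maps to reference position k.
#'
#' @param aln An alignment from [as_msa()].
#' @param ref_id Row id of the reference sequence.
#' @return An object of class `reference_map`: list with `ref_id`,
#'   `ref_row` (the aligned reference characters), `col_to_ref` (integer
#'   vector over columns, `NA` where the reference is gapped) and
#'   `ref_to_col` (inverse, over reference positions).
#' @export
build_reference_map <- function(aln, ref_id) {
  aln <- as_msa(aln)
  if (!ref_id %in% rownames(aln)) {
    stop("reference id '", ref_id, "' is not an alignment row", call. = FALSE)
  }
  ref_row <- unclass(aln)[ref_id, ]
  non_gap <- !(ref_row %in% c("-", "."))
  col_to_ref <- rep(NA_integer_, length(ref_row))
  col_to_ref[non_gap] <- seq_len(sum(non_gap))
  structure(list(ref_id = ref_id, ref_row = ref_row,
                 col_to_ref = col_to_ref,
                 ref_to_col = which(non_gap)),
            class = "reference_map")
}

#' @export
print.reference_map <- function(x, ...) {
  cat("<reference_map> reference '", x$ref_id, "': ",
      length(x$ref_to_col), " residues over ", length(x$col_to_ref),
      " alignment columns\n", sep = "")
  invisible(x)
}

#' The ungapped reference protein sequence
#'
#' @param map A `reference_map`.
#' @return Single string: the reference row with gaps removed.
#' @export
reference_sequence <- function(map) {
  stopifnot(inherits(map, "reference_map"))
  paste(map$ref_row[map$ref_to_col], collapse = "")
}

#' Build a trivial reference map from an ungapped sequence
#'
#' For workflows where samples are placed directly on a reference protein
#' (no multiple alignment), the map is the identity on `1..nchar(seq)`.
#'
#' @param seq Ungapped reference protein string.
#' @param ref_id Identifier to record for the reference.
#' @return A `reference_map`.
#' @export
reference_map_from_sequence <- function(seq, ref_id = "reference") {
  stopifnot(length(seq) == 1L, nchar(seq) >= 1L)
  chars <- strsplit(toupper(seq), "")[[1]]
  if (any(chars %in% c("-", "."))) {
    stop("reference sequence must be ungapped", call. = FALSE)
  }
  structure(list(ref_id = ref_id, ref_row = chars,
                 col_to_ref = seq_along(chars),
                 ref_to_col = seq_along(chars)),
            class = "reference_map")
}

#' Attach reference positions to columns
#'
#' Annotates an edge report (or a bare vector of columns) with the reference
#' position of each column; columns where the reference is gapped are marked
#' unmapped (`NA`). When a per-gene offset table from
#' [concatenate_proteomes()] is supplied, positions are additionally
#' reported as (gene, within-gene reference position).
#'
#' @param x An `edge_report` from [focal_edge_report()], or an integer
#'   vector of alignment columns.
#' @param map A `reference_map` built from the same alignment.
#' @param offsets Optional offset data.frame (`gene`, `start`, `end`).
#' @return For a report: the report with a `ref_position` column (and
#'   `gene`/`gene_position` when offsets are given). For a vector: a
#'   data.frame `column`, `ref_position` (+ gene columns).
#' @export
annotate_with_reference <- function(x, map, offsets = NULL) {
  stopifnot(inherits(map, "reference_map"))
  cols <- if (is.data.frame(x)) x$column else as.integer(x)
  if (any(cols < 1L | cols > length(map$col_to_ref))) {
    stop("column out of range of the reference map", call. = FALSE)
  }
  ref_pos <- map$col_to_ref[cols]
  out <- if (is.data.frame(x)) x else data.frame(column = cols)
  out$ref_position <- ref_pos
  if (!is.null(offsets)) {
    gi <- vapply(cols, function(cc) {
      hit <- which(offsets$start <= cc & cc <= offsets$end)
      if (length(hit) == 0L) NA_integer_ else hit[1]
    }, integer(1))
    out$gene <- ifelse(is.na(gi), NA_character_, offsets$gene[gi])
    # reference residues counted before each gene block give the gene-local origin
    prior <- vapply(seq_len(nrow(offsets)), function(i) {
      if (offsets$start[i] <= 1L) 0L else {
        sum(!is.na(map$col_to_ref[seq_len(offsets$start[i] - 1L)]))
      }
    }, integer(1))
    out$gene_position <- ifelse(is.na(gi) | is.na(ref_pos), NA_integer_,
                                ref_pos - prior[gi])
  }
  out
}

#' Look up the alignment column of a reference position
#'
#' @param map A `reference_map`.
#' @param ref_position 1-based position(s) in the ungapped reference.
#' @return Integer alignment column(s).
#' @export
reference_to_column <- function(map, ref_position) {
  stopifnot(inherits(map, "reference_map"))
  if (any(ref_position < 1L | ref_position > length(map$ref_to_col))) {
    stop("reference position out of range 1..", length(map$ref_to_col),
         call. = FALSE)
  }
  map$ref_to_col[ref_position]
}

#' Write a reference map as TSV
#'
#' @param map A `reference_map`.
#' @param path Output path.
#' @param offsets Optional gene offset table to add gene columns.
#' @return `path`, invisibly.
#' @export
write_reference_map <- function(map, path, offsets = NULL) {
  tab <- annotate_with_reference(seq_along(map$col_to_ref), map, offsets)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
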