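# Residue alphabets accepted on input. '.' is normalised to '-' when read.
.AA_ALPHABET <- c(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], "X", "*", "-")
.NT_ALPHABET <- c(strsplit("ACGTUNRYSWKMBDHV", "")[[1]], "-")

#' Read a FASTA file
#'
#' Parses a (wrapped or unwrapped) multi-record FASTA file into a named
#' character vector of upper-case sequences. The record id is the first
#' whitespace-delimited token of each header. Gaps (`-`) are preserved and
#' `.` is normalised to `-`.
#'
#' @param path Path to a FASTA file.
#' @param alphabet `"aa"` for amino acids (default) or `"nt"` for
#'   nucleotides; sequences are validated against the chosen alphabet.
#' @return A named character vector, one element per record.
#' @export
read_fasta <- function(path, alphabet = c("aa", "nt")) {
  alphabet <- match.arg(alphabet)
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("empty FASTA file: ", path, call. = FALSE)
  is_hdr <- startsWith(lines, ">")
  if (!is_hdr[1]) stop("not FASTA: first line is not a header in ", path,
                       call. = FALSE)
  grp <- cumsum(is_hdr)
  headers <- sub("^>\\s*", "", lines[is_hdr])
  ids <- vapply(strsplit(headers, "\\s+"), `[`, character(1), 1L)
  if (anyNA(ids) || any(!nzchar(ids))) {
    stop("FASTA record with empty id in ", path, call. = FALSE)
  }
  dup <- unique(ids[duplicated(ids)])
  if (length(dup) > 0L) {
    stop("duplicate FASTA id(s): ", paste(dup, collapse = ", "), call. = FALSE)
  }
  seqs <- vapply(split(lines[!is_hdr], factor(grp[!is_hdr], levels = seq_along(ids))),
                 paste, character(1), collapse = "")
  seqs <- toupper(chartr(".", "-", seqs))
  empty <- ids[!nzchar(seqs)]
  if (length(empty) > 0L) {
    stop("record(s) with empty sequence: ", paste(empty, collapse = ", "),
         call. = FALSE)
  }
  allowed <- if (alphabet == "aa") .AA_ALPHABET else .NT_ALPHABET
  for (i in seq_along(seqs)) {
    chars <- unique(strsplit(seqs[[i]], "")[[1]])
    bad <- setdiff(chars, allowed)
    if (length(bad) > 0L) {
      stop("illegal ", alphabet, " character(s) '", paste(bad, collapse = "', '"),
           "' in record '", ids[i], "'", call. = FALSE)
    }
  }
  names(seqs) <- ids
  seqs
}

#' Write sequences to a FASTA file
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @param width Line-wrap width (default 70).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 70) {
  stopifnot(!is.null(names(seqs)), all(nzchar(names(seqs))))
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    writeLines(paste0(">", names(seqs)[i]), con)
    s <- seqs[[i]]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' Build an alignment matrix from equal-length sequences
#'
#' The package's working representation of a multiple alignment is a
#' character matrix with one row per sequence (rownames are the ids) and one
#' single-character column per alignment column, columns indexed 1-based.
#'
#' @param seqs Named character vector of equal-length aligned sequences, or
#'   an already-built character matrix (returned unchanged after checks).
#' @return A character matrix of class `msa`.
#' @export
as_msa <- function(seqs) {
  if (is.matrix(seqs)) {
    m <- seqs
  } else {
    stopifnot(is.character(seqs), !is.null(names(seqs)))
    lens <- nchar(seqs)
    if (length(unique(lens)) != 1L) {
      stop("aligned sequences must all have the same length; got lengths ",
           paste(sort(unique(lens)), collapse = ", "), call. = FALSE)
    }
    m <- do.call(rbind, strsplit(toupper(chartr(".", "-", seqs)), ""))
    rownames(m) <- names(seqs)
  }
  if (nrow(m) < 2L) stop("an alignment needs at least 2 rows", call. = FALSE)
  if (ncol(m) < 1L) stop("an alignment needs at least 1 column", call. = FALSE)
  if (anyDuplicated(rownames(m))) stop("duplicate alignment row ids",
                                       call. = FALSE)
  class(m) <- c("msa", class(m))
  m
}

#' Collapse an alignment matrix back to strings
#'
#' @param aln An alignment matrix from [as_msa()].
#' @return Named character vector of aligned sequences.
#' @export
msa_to_strings <- function(aln) {
  apply(unclass(aln), 1L, paste, collapse = "")
}

#' Concatenate per-gene sequences into one record per species
#'
#' Mirrors the construction of a concatenated mitochondrial proteome
#' alignment: for each species the genes are joined in a fixed order, and an
#' offset table records where each gene starts and ends within the
#' concatenation (1-based, inclusive). Each gene must have a consistent
#' length across species (i.e. the per-gene sequences are pre-aligned).
#'
#' @param per_species Named list (species) of named lists/character vectors
#'   (gene -> sequence string).
#' @param gene_order Character vector giving the concatenation order.
#' @param missing Policy for a species lacking a gene: `"error"` (default)
#'   or `"pad"` (fill with gaps of the gene's length).
#' @return A list with `records` (named character vector, one concatenated
#'   sequence per species) and `offsets` (data.frame gene/start/end).
#' @export
concatenate_proteomes <- function(per_species, gene_order,
                                  missing = c("error", "pad")) {
  missing <- match.arg(missing)
  stopifnot(length(per_species) >= 1L, length(gene_order) >= 1L)
  gene_len <- integer(0)
  for (g in gene_order) {
    lens <- unique(unlist(lapply(per_species, function(sp) {
      if (g %in% names(sp)) nchar(sp[[g]]) else NULL
    })))
    if (length(lens) == 0L) {
      stop("gene '", g, "' is absent from every species", call. = FALSE)
    }
    if (length(lens) > 1L) {
      stop("gene '", g, "' has inconsistent lengths across species: ",
           paste(sort(lens), collapse = ", "), call. = FALSE)
    }
    gene_len[g] <- lens
  }
  ends <- cumsum(gene_len[gene_order])
  starts <- ends - gene_len[gene_order] + 1L
  records <- vapply(names(per_species), function(spn) {
    sp <- per_species[[spn]]
    pieces <- vapply(gene_order, function(g) {
      if (g %in% names(sp)) {
        sp[[g]]
      } else if (missing == "pad") {
        strrep("-", gene_len[g])
      } else {
        stop("species '", spn, "' is missing gene '", g,
             "' (use missing = \"pad\" to gap-fill)", call. = FALSE)
      }
    }, character(1))
    paste(pieces, collapse = "")
  }, character(1))
  list(records = records,
       offsets = data.frame(gene = gene_order, start = unname(starts),
                            end = unname(ends), stringsAsFactors = FALSE))
}

#' Read a clade annotation table
#'
#' Reads the tab-separated annotation format used throughout the package:
#' a header row, column 1 the sequence id, remaining columns clade labels
#' (e.g. order, family, genus, species).
#'
#' @param path Path to the TSV file.
#' @return A data.frame with the id column named `id`.
#' @export
read_annotations <- function(path) {
  ann <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (ncol(ann) < 2L) stop("annotation table needs an id column plus at least ",
                           "one clade column", call. = FALSE)
  names(ann)[1] <- "id"
  if (anyDuplicated(ann$id)) stop("duplicate sample ids in annotation table",
                                  call. = FALSE)
  ann
}
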