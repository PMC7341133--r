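#' Genetic code tables
#'
#' Embedded codon tables matching NCBI translation tables 1 (standard),
#' 2 (vertebrate mitochondrial) and 5 (invertebrate mitochondrial). Tables
#' are built into the package so that no network or external resource is
#' needed; stop codons map to the distinguished symbol `"*"`.
#'
#' @param code_id One of `"standard"`, `"vertebrate-mitochondrial"`,
#'   `"invertebrate-mitochondrial"`, or the corresponding NCBI table numbers
#'   `"1"`, `"2"`, `"5"`.
#' @return An object of class `genetic_code`: a list with `code_id` and
#'   `table`, a named character vector of 64 entries mapping codons
#'   (e.g. `"GCT"`) to one-letter amino acids or `"*"` for stop.
#' @examples
#' code <- genetic_code("vertebrate-mitochondrial")
#' code$table[["TGA"]]  # "W" in the vertebrate mitochondrial code
#' @export
genetic_code <- function(code_id = "vertebrate-mitochondrial") {
  key <- .resolve_code_id(code_id)
  aas <- .CODE_STRINGS[[key]]
  tab <- strsplit(aas, "")[[1]]
  names(tab) <- .CODON_ORDER
  structure(list(code_id = key, table = tab), class = "genetic_code")
}

# NCBI ttable amino-acid strings in the canonical TCAG codon order.
.CODE_STRINGS <- c(
  "standard" =
    "FFLLSSSSYY**CC*WLLLLPPPPHHQQRRRRIIIMTTTTNNKKSSRRVVVVAAAADDEEGGGG",
  "vertebrate-mitochondrial" =
    "FFLLSSSSYY**CCWWLLLLPPPPHHQQRRRRIIMMTTTTNNKKSS**VVVVAAAADDEEGGGG",
  "invertebrate-mitochondrial" =
    "FFLLSSSSYY**CCWWLLLLPPPPHHQQRRRRIIMMTTTTNNKKSSSSVVVVAAAADDEEGGGG"
)

.CODON_ORDER <- {
  b <- c("T", "C", "A", "G")
  paste0(rep(b, each = 16), rep(rep(b, each = 4), 4), rep(b, 16))
}

.resolve_code_id <- function(code_id) {
  aliases <- c("1" = "standard", "2" = "vertebrate-mitochondrial",
               "5" = "invertebrate-mitochondrial")
  id <- as.character(code_id)
  if (id %in% names(aliases)) id <- aliases[[id]]
  if (!id %in% names(.CODE_STRINGS)) {
    stop("unknown genetic code id: '", code_id, "' (expected ",
         paste(c(names(.CODE_STRINGS), names(aliases)), collapse = ", "), ")",
         call. = FALSE)
  }
  id
}

#' @export
print.genetic_code <- function(x, ...) {
  cat("<genetic_code>", x$code_id, "\n")
  stops <- names(x$table)[x$table == "*"]
  cat("  stop codons:", paste(stops, collapse = " "), "\n")
  invisible(x)
}

#' Translate a nucleotide sequence
#'
#' Translates one reading frame of a nucleotide sequence under a chosen
#' genetic code. Codons containing `N`, a gap, or any other ambiguous
#' character translate to `"X"`; a trailing partial codon is dropped.
#'
#' @param seq A single nucleotide string (characters `A,C,G,T,U,N,-` plus
#'   IUPAC ambiguity letters; case-insensitive; `.` is read as `-`).
#' @param code A [genetic_code()] object or a code id string.
#' @param frame Reading frame, 1, 2 or 3.
#' @return The amino-acid string, one residue per complete codon, with
#'   `"*"` marking stops and `"X"` marking ambiguous codons.
#' @examples
#' translate("GCCAGAACT", genetic_code("vertebrate-mitochondrial"))
#' @export
translate <- function(seq, code = genetic_code(), frame = 1) {
  if (is.character(code) && !inherits(code, "genetic_code")) {
    code <- genetic_code(code)
  }
  stopifnot(length(seq) == 1L, frame %in% 1:3)
  s <- chartr("u.", "t-", tolower(seq))
  s <- toupper(s)
  s <- substring(s, frame)
  n_codon <- nchar(s) %/% 3L
  if (n_codon == 0L) {
    stop("sequence too short to contain a codon in frame ", frame,
         call. = FALSE)
  }
  codons <- substring(s, 3L * seq_len(n_codon) - 2L, 3L * seq_len(n_codon))
  aa <- unname(code$table[codons])
  aa[is.na(aa)] <- "X"  # any codon not in the table (N, gap, IUPAC) is ambiguous
  paste(aa, collapse = "")
}

#' Choose the reading frame of an unoriented barcode
#'
#' Translates all three frames and picks the one with the fewest internal
#' stop codons (ties broken toward the lowest frame number), the usual
#' heuristic for barcode fragments whose frame is unknown.
#'
#' @inheritParams translate
#' @return A list with `frame` and the translated `protein`.
#' @export
best_frame_translation <- function(seq, code = genetic_code()) {
  if (is.character(code) && !inherits(code, "genetic_code")) {
    code <- genetic_code(code)
  }
  prots <- lapply(1:3, function(f) translate(seq, code, frame = f))
  # internal stops only: a terminal stop is legitimate
  n_stop <- vapply(prots, function(p) {
    body <- substr(p, 1L, max(nchar(p) - 1L, 0L))
    lengths(regmatches(body, gregexpr("\\*", body)))
  }, integer(1))
  f <- which.min(n_stop)  # which.min takes the first (= lowest frame) on ties
  list(frame = f, protein = prots[[f]])
}

#' Minimum codon distance between two amino acids
#'
#' The minimum Hamming distance between any codon encoding `aa1` and any
#' codon encoding `aa2` under a given code. A distance of 1 means the two
#' amino acids are separated by a single base-pair alteration.
#'
#' @param aa1,aa2 One-letter amino-acid codes (`"*"` allowed for stop).
#' @param code A [genetic_code()] object or code id.
#' @return Integer minimum Hamming distance (0 when `aa1 == aa2`).
#' @examples
#' min_codon_distance("A", "S")  # alanine and serine are one change apart
#' @export
min_codon_distance <- function(aa1, aa2, code = genetic_code()) {
  if (is.character(code) && !inherits(code, "genetic_code")) {
    code <- genetic_code(code)
  }
  c1 <- names(code$table)[code$table == toupper(aa1)]
  c2 <- names(code$table)[code$table == toupper(aa2)]
  if (length(c1) == 0L) {
    stop("amino acid '", aa1, "' is not encoded by code ", code$code_id,
         call. = FALSE)
  }
  if (length(c2) == 0L) {
    stop("amino acid '", aa2, "' is not encoded by code ", code$code_id,
         call. = FALSE)
  }
  m1 <- do.call(rbind, strsplit(c1, ""))
  m2 <- do.call(rbind, strsplit(c2, ""))
  best <- 3L
  for (i in seq_len(nrow(m1))) {
    d <- rowSums(m2 != matrix(m1[i, ], nrow(m2), 3L, byrow = TRUE))
    best <- min(best, d)
    if (best == 0L) break
  }
  as.integer(best)
}

#' Back-translate a protein to nucleotides with random synonymous codons
#'
#' Each residue is replaced by a codon drawn uniformly from its synonymous
#' codons under `code`. `X` and gap residues become `NNN`. Used by the
#' synthetic barcode generator; `translate()` inverts it exactly.
#'
#' @param protein Amino-acid string.
#' @param code A [genetic_code()] object or code id.
#' @return A nucleotide string of length `3 * nchar(protein)`.
#' @export
back_translate <- function(protein, code = genetic_code()) {
  if (is.character(code) && !inherits(code, "genetic_code")) {
    code <- genetic_code(code)
  }
  aa <- strsplit(toupper(protein), "")[[1]]
  codons <- vapply(aa, function(a) {
    if (a %in% c("X", "-", ".")) return("NNN")
    syn <- names(code$table)[code$table == a]
    if (length(syn) == 0L) {
      stop("residue '", a, "' is not encoded by code ", code$code_id,
           call. = FALSE)
    }
    syn[sample.int(length(syn), 1L)]
  }, character(1), USE.NAMES = FALSE)
  paste(codons, collapse = "")
}
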