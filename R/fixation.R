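# cache for the substitution matrix shipped with Biostrings
.pkg_cache <- new.env(parent = emptyenv())

.blosum62 <- function() {
  if (is.null(.pkg_cache$BLOSUM62)) {
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    .pkg_cache$BLOSUM62 <- e$BLOSUM62
  }
  .pkg_cache$BLOSUM62
}

#' Place translated barcodes on a reference protein
#'
#' Aligns each amino-acid fragment to the ungapped reference protein with a
#' local affine-gap pairwise alignment (BLOSUM62, gap opening 10, gap
#' extension 0.5 — the only alignment computed in the package, needed
#' because barcode fragments arrive unaligned) and reads off the residue
#' each fragment carries at a given reference position.
#'
#' @param proteins Named character vector of translated fragments.
#' @param ref_protein Ungapped reference protein string.
#' @param ref_position 1-based position in the reference protein.
#' @return Named character vector: the residue of each fragment aligned to
#'   `ref_position`, `"-"` where the fragment has a gap there and `NA` where
#'   its aligned span does not cover the position.
#' @export
place_on_reference <- function(proteins, ref_protein, ref_position) {
  stopifnot(length(ref_protein) == 1L,
            ref_position >= 1L, ref_position <= nchar(ref_protein))
  pa <- Biostrings::pairwiseAlignment(
    pattern = Biostrings::AAStringSet(unname(proteins)),
    subject = Biostrings::AAString(ref_protein),
    type = "local", substitutionMatrix = .blosum62(),
    gapOpening = 10, gapExtension = 0.5)
  gp <- as.character(Biostrings::alignedPattern(pa))
  gs <- as.character(Biostrings::alignedSubject(pa))
  s_start <- Biostrings::start(Biostrings::subject(pa))
  out <- vapply(seq_along(gp), function(i) {
    schars <- strsplit(gs[i], "")[[1]]
    pchars <- strsplit(gp[i], "")[[1]]
    spos <- s_start[i] - 1L + cumsum(schars != "-")
    hit <- which(spos == ref_position & schars != "-")
    if (length(hit) == 0L) NA_character_ else pchars[hit[1]]
  }, character(1))
  names(out) <- names(proteins)
  out
}

#' Classify clade-level fixation from a residue spectrum
#'
#' @param spectrum Named integer vector of residue counts over informative
#'   samples.
#' @param ancestral_residue The residue considered ancestral at the
#'   position.
#' @param threshold Fraction of informative samples a residue must reach to
#'   be called fixed; must lie in (0.5, 1] (default 1: strictly universal).
#' @return A list with `status` (`"fixed"`, `"unfixed"` or `"absent"`),
#'   `residue` (the fixed residue or `NA`), `derived` (`TRUE` when the fixed
#'   residue differs from the ancestral one) and `fraction` (frequency of
#'   the majority residue, `NA` when absent).
#' @export
classify_fixation <- function(spectrum, ancestral_residue, threshold = 1.0) {
  if (threshold <= 0.5 || threshold > 1) {
    stop("threshold must lie in (0.5, 1]", call. = FALSE)
  }
  n <- sum(spectrum)
  if (length(spectrum) == 0L || n == 0L) {
    return(list(status = "absent", residue = NA_character_, derived = FALSE,
                fraction = NA_real_))
  }
  top <- which.max(spectrum)
  frac <- spectrum[[top]] / n
  if (frac >= threshold) {
    res <- names(spectrum)[top]
    list(status = "fixed", residue = res,
         derived = if (is.null(ancestral_residue)) NA else
           !identical(res, ancestral_residue),
         fraction = frac)
  } else {
    list(status = "unfixed", residue = NA_character_, derived = FALSE,
         fraction = frac)
  }
}

.format_fixation <- function(fx) {
  switch(fx$status,
         fixed = paste0("fixed(", fx$residue, ")"),
         fx$status)
}

#' Survey residue occupancy at a reference position across clades
#'
#' Tabulates, for every clade in an annotation table, the residues carried
#' at one reference position by a panel of samples, applying the
#' informativeness rule: a sample is informative when its (aligned or
#' placed) sequence shows a standard amino acid — not a gap, not `X`, not a
#' stop, not a truncation — at the mapped position. Non-covering and
#' ambiguous samples stay in `n_total` but are excluded from
#' `n_informative`.
#'
#' @param samples Named character vector. With `aligned = TRUE`, amino-acid
#'   rows in the same column coordinates as `map`. Otherwise nucleotide
#'   barcode fragments, which are translated (frame chosen by
#'   [best_frame_translation()]) and placed on the reference protein by
#'   [place_on_reference()].
#' @param annotations Data.frame with an `id` column (see
#'   [read_annotations()]).
#' @param map A `reference_map` for the coordinate system.
#' @param ref_position 1-based reference position to survey.
#' @param clade_column Name of the annotation column defining clades
#'   (default: the first non-id column).
#' @param ancestral_residue Residue treated as ancestral when classifying
#'   fixation.
#' @param threshold Fixation threshold, see [classify_fixation()].
#' @param aligned Whether `samples` are pre-aligned to the map coordinates.
#' @param code Genetic code for barcode translation (object or id).
#' @param exclude Optional character vector of sample ids to drop entirely
#'   (e.g. known mis-annotated entries).
#' @return A data.frame of class `fixation_report`: one row per clade with
#'   `clade`, `n_total`, `n_informative`, `fixation_state`, `derived`,
#'   `fraction` and a `spectrum` list-column; attributes record
#'   `ref_position`, `ancestral_residue` and `threshold`.
#' @export
survey_position <- function(samples, annotations, map, ref_position,
                            clade_column = NULL, ancestral_residue = NULL,
                            threshold = 1.0, aligned = FALSE,
                            code = genetic_code(), exclude = NULL) {
  stopifnot(inherits(map, "reference_map"), !is.null(names(samples)))
  if (ref_position < 1L || ref_position > length(map$ref_to_col)) {
    stop("reference position ", ref_position, " is unmapped (reference has ",
         length(map$ref_to_col), " residues)", call. = FALSE)
  }
  if (!"id" %in% names(annotations)) names(annotations)[1] <- "id"
  if (is.null(clade_column)) clade_column <- setdiff(names(annotations), "id")[1]
  if (!clade_column %in% names(annotations)) {
    stop("no annotation column '", clade_column, "'", call. = FALSE)
  }
  if (!is.null(exclude)) {
    samples <- samples[!names(samples) %in% exclude]
    annotations <- annotations[!annotations$id %in% exclude, , drop = FALSE]
  }
  unknown <- setdiff(names(samples), annotations$id)
  if (length(unknown) > 0L) {
    stop("sample(s) without annotation: ",
         paste(utils::head(unknown, 5), collapse = ", "), call. = FALSE)
  }

  if (aligned) {
    column <- reference_to_column(map, ref_position)
    residues <- toupper(substr(samples, column, column))
    residues[!nzchar(residues)] <- NA_character_
  } else {
    prots <- vapply(samples, function(s) best_frame_translation(s, code)$protein,
                    character(1))
    residues <- place_on_reference(prots, reference_sequence(map), ref_position)
  }
  residues <- normalize_missing(ifelse(is.na(residues), "X", residues))

  clades <- annotations[[clade_column]][match(names(samples), annotations$id)]
  rows <- lapply(sort(unique(clades)), function(cl) {
    res <- residues[clades == cl]
    informative <- res %in% .AA20
    spec <- table(factor(res[informative]))
    spec <- stats::setNames(as.integer(spec), names(spec))
    spec <- sort(spec, decreasing = TRUE)
    fx <- classify_fixation(spec, ancestral_residue, threshold)
    data.frame(clade = cl, n_total = length(res),
               n_informative = sum(informative),
               fixation_state = .format_fixation(fx),
               derived = fx$derived, fraction = fx$fraction,
               spectrum = I(list(spec)), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out, class = c("fixation_report", "data.frame"),
            ref_position = ref_position,
            ancestral_residue = ancestral_residue, threshold = threshold)
}

#' Merge fixation reports over disjoint sample sets
#'
#' Componentwise addition of `n_total`, `n_informative` and spectra for
#' reports produced at the same reference position with the same ancestral
#' residue and threshold; fixation is re-classified on the merged spectra.
#'
#' @param a,b `fixation_report` objects.
#' @return A merged `fixation_report`.
#' @export
merge_fixation_reports <- function(a, b) {
  stopifnot(inherits(a, "fixation_report"), inherits(b, "fixation_report"),
            identical(attr(a, "ref_position"), attr(b, "ref_position")),
            identical(attr(a, "threshold"), attr(b, "threshold")))
  anc <- attr(a, "ancestral_residue")
  clades <- sort(union(a$clade, b$clade))
  rows <- lapply(clades, function(cl) {
    ia <- match(cl, a$clade); ib <- match(cl, b$clade)
    spec_a <- if (is.na(ia)) integer(0) else a$spectrum[[ia]]
    spec_b <- if (is.na(ib)) integer(0) else b$spectrum[[ib]]
    res <- union(names(spec_a), names(spec_b))
    spec <- stats::setNames(
      ifelse(res %in% names(spec_a), spec_a[res], 0L) +
        ifelse(res %in% names(spec_b), spec_b[res], 0L), res)
    spec <- sort(as.integer(spec) |> stats::setNames(res), decreasing = TRUE)
    fx <- classify_fixation(spec, anc, attr(a, "threshold"))
    data.frame(clade = cl,
               n_total = sum(a$n_total[ia], b$n_total[ib], na.rm = TRUE),
               n_informative = sum(a$n_informative[ia], b$n_informative[ib],
                                   na.rm = TRUE),
               fixation_state = .format_fixation(fx), derived = fx$derived,
               fraction = fx$fraction, spectrum = I(list(spec)),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out, class = class(a), ref_position = attr(a, "ref_position"),
            ancestral_residue = anc, threshold = attr(a, "threshold"))
}

#' Rank clades carrying non-ancestral residues
#'
#' Restricts a fixation report to clades with at least one informative
#' sample divergent from the ancestral residue, ranked by derived fraction
#' (descending), and reports the overall divergent-sample count and
#' fraction across all informative samples.
#'
#' @param report A `fixation_report`.
#' @return A data.frame `clade`, `n_informative`, `n_derived`,
#'   `derived_fraction`, with attributes `overall_divergent`,
#'   `overall_informative` and `overall_fraction`.
#' @export
rank_substituted_clades <- function(report) {
  stopifnot(inherits(report, "fixation_report"))
  anc <- attr(report, "ancestral_residue")
  if (is.null(anc)) stop("report has no ancestral residue set", call. = FALSE)
  n_derived <- vapply(report$spectrum, function(sp) {
    sum(sp[setdiff(names(sp), anc)])
  }, numeric(1))
  keep <- n_derived > 0
  out <- data.frame(clade = report$clade[keep],
                    n_informative = report$n_informative[keep],
                    n_derived = as.integer(n_derived[keep]))
  out$derived_fraction <- ifelse(out$n_informative > 0,
                                 out$n_derived / out$n_informative, 0)
  out <- out[order(-out$derived_fraction, out$clade), , drop = FALSE]
  rownames(out) <- NULL
  total_inf <- sum(report$n_informative)
  total_div <- sum(n_derived)
  structure(out, overall_divergent = as.integer(total_div),
            overall_informative = as.integer(total_inf),
            overall_fraction = if (total_inf > 0) total_div / total_inf else 0)
}

#' Write a fixation report as TSV
#'
#' One row per clade with residue counts spread into columns, mirroring a
#' per-clade fixation table.
#'
#' @param report A `fixation_report`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fixation_report <- function(report, path) {
  residues <- sort(unique(unlist(lapply(report$spectrum, names))))
  counts <- vapply(report$spectrum, function(sp) {
    vapply(residues, function(r) if (r %in% names(sp)) sp[[r]] else 0L,
           integer(1))
  }, integer(length(residues)))
  tab <- data.frame(clade = report$clade, n_total = report$n_total,
                    n_informative = report$n_informative,
                    stringsAsFactors = FALSE)
  if (length(residues) > 0L) {
    cm <- if (is.matrix(counts)) t(counts) else matrix(counts, ncol = 1)
    colnames(cm) <- residues
    tab <- cbind(tab, cm)
  }
  tab$fixation_state <- report$fixation_state
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
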