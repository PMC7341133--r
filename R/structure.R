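#' Read a macromolecular structure (PDB or mmCIF)
#'
#' Parses ATOM/HETATM records into an atom table. Hydrogens are excluded by
#' default (distance annotation uses heavy atoms); alternate locations are
#' resolved to the highest-occupancy conformer, ties going to altloc `A`
#' (then alphabetical).
#'
#' @param path Path to a PDB (`.pdb`, `.ent`) or mmCIF (`.cif`) file; the
#'   format is detected from the content when the extension is ambiguous.
#' @param keep_hydrogens Retain hydrogen atoms (default `FALSE`).
#' @return An object of class `structure_model`: a data.frame with columns
#'   `record`, `atom`, `altloc`, `resname`, `chain`, `resseq`, `x`, `y`,
#'   `z`, `occupancy`, `element`.
#' @export
read_structure <- function(path, keep_hydrogens = FALSE) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  is_cif <- grepl("\\.cif(\\.gz)?$", path, ignore.case = TRUE) ||
    any(startsWith(lines, "_atom_site."))
  atoms <- if (is_cif) .parse_cif_atoms(lines) else .parse_pdb_atoms(lines)
  if (nrow(atoms) == 0L) stop("no ATOM/HETATM records in ", path,
                              call. = FALSE)
  if (!keep_hydrogens) {
    elem <- atoms$element
    blank <- !nzchar(elem)
    # fall back on the first alphabetic character of the atom name
    elem[blank] <- sub("^[0-9]*", "", atoms$atom[blank])
    elem[blank] <- substr(elem[blank], 1L, 1L)
    atoms <- atoms[!toupper(elem) %in% c("H", "D"), , drop = FALSE]
  }
  # resolve altlocs: keep the highest-occupancy conformer per atom site
  key <- paste(atoms$chain, atoms$resseq, atoms$resname, atoms$atom, sep = "|")
  ord <- order(key, -atoms$occupancy, atoms$altloc)
  atoms <- atoms[ord, , drop = FALSE]
  atoms <- atoms[!duplicated(key[ord]), , drop = FALSE]
  atoms <- atoms[order(atoms$chain, atoms$resseq, atoms$atom), , drop = FALSE]
  rownames(atoms) <- NULL
  if (any(!is.finite(atoms$x) | !is.finite(atoms$y) | !is.finite(atoms$z))) {
    stop("non-finite coordinates in ", path, call. = FALSE)
  }
  structure(atoms, class = c("structure_model", "data.frame"))
}

.parse_pdb_atoms <- function(lines) {
  rec <- substr(lines, 1, 6)
  keep <- rec %in% c("ATOM  ", "HETATM")
  l <- lines[keep]
  data.frame(
    record = trimws(substr(l, 1, 6)),
    atom = trimws(substr(l, 13, 16)),
    altloc = trimws(substr(l, 17, 17)),
    resname = trimws(substr(l, 18, 20)),
    chain = trimws(substr(l, 22, 22)),
    resseq = suppressWarnings(as.integer(substr(l, 23, 26))),
    x = as.numeric(substr(l, 31, 38)),
    y = as.numeric(substr(l, 39, 46)),
    z = as.numeric(substr(l, 47, 54)),
    occupancy = {
      o <- suppressWarnings(as.numeric(substr(l, 55, 60)))
      ifelse(is.na(o), 1, o)
    },
    element = toupper(trimws(substr(l, 77, 78))),
    stringsAsFactors = FALSE)
}

.parse_cif_atoms <- function(lines) {
  hdr_idx <- which(startsWith(trimws(lines), "_atom_site."))
  if (length(hdr_idx) == 0L) stop("no _atom_site loop in mmCIF input",
                                  call. = FALSE)
  fields <- sub("^_atom_site\\.", "", trimws(lines[hdr_idx]))
  body_start <- max(hdr_idx) + 1L
  body <- character(0)
  for (i in body_start:length(lines)) {
    ln <- trimws(lines[i])
    if (startsWith(ln, "ATOM") || startsWith(ln, "HETATM")) {
      body <- c(body, ln)
    } else if (nzchar(ln) && !startsWith(ln, "#")) break
  }
  toks <- strsplit(body, "\\s+")
  get <- function(row, field, default = "") {
    j <- match(field, fields)
    if (is.na(j) || j > length(row)) default else row[j]
  }
  do.call(rbind, lapply(toks, function(row) {
    data.frame(
      record = get(row, "group_PDB"),
      atom = gsub('"', "", get(row, "label_atom_id")),
      altloc = sub("^[.?]$", "", get(row, "label_alt_id")),
      resname = get(row, "label_comp_id"),
      chain = {
        ch <- get(row, "auth_asym_id")
        if (nzchar(ch)) ch else get(row, "label_asym_id")
      },
      resseq = {
        rs <- get(row, "auth_seq_id")
        as.integer(if (nzchar(rs) && rs != ".") rs else get(row, "label_seq_id"))
      },
      x = as.numeric(get(row, "Cartn_x")),
      y = as.numeric(get(row, "Cartn_y")),
      z = as.numeric(get(row, "Cartn_z")),
      occupancy = {
        o <- suppressWarnings(as.numeric(get(row, "occupancy", "1")))
        if (is.na(o)) 1 else o
      },
      element = toupper(get(row, "type_symbol")),
      stringsAsFactors = FALSE)
  }))
}

#' @export
print.structure_model <- function(x, ...) {
  cat("<structure_model> ", nrow(x), " atoms, chains: ",
      paste(sort(unique(x$chain)), collapse = " "), "\n", sep = "")
  invisible(x)
}

.residue_coords <- function(model, chain, resseq) {
  sel <- model$chain == chain & model$resseq == resseq
  if (!any(sel)) {
    stop("residue ", resseq, " not found in chain ", chain, call. = FALSE)
  }
  as.matrix(model[sel, c("x", "y", "z"), drop = FALSE])
}

#' Minimum inter-residue heavy-atom distance
#'
#' The minimum Euclidean distance (in Angstrom) over all atom pairs drawn
#' one from each residue. With the default hydrogen-free model this is the
#' minimum heavy-atom distance, which makes "within X Angstrom" statements
#' testable as upper bounds.
#'
#' @param model A `structure_model`.
#' @param chain Chain identifier.
#' @param resA,resB Residue numbers within the chain.
#' @return Distance in Angstrom (0 when `resA == resB`).
#' @export
min_residue_distance <- function(model, chain, resA, resB) {
  stopifnot(inherits(model, "structure_model"))
  if (resA == resB) {
    .residue_coords(model, chain, resA)  # still validate presence
    return(0)
  }
  a <- .residue_coords(model, chain, resA)
  b <- .residue_coords(model, chain, resB)
  d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * tcrossprod(a, b)
  sqrt(max(min(d2), 0))
}

#' Distance table of candidate positions against landmarks
#'
#' Minimum heavy-atom distances of each candidate residue to each landmark
#' residue (e.g. proton-channel landmarks such as D91, N80 and E242 in a
#' cytochrome c oxidase structure).
#'
#' @param model A `structure_model`.
#' @param chain Chain identifier; `NULL` picks the first chain containing
#'   all queried residues.
#' @param positions Integer vector of candidate residue numbers.
#' @param landmarks Integer vector of landmark residue numbers.
#' @return Numeric matrix (`positions` x `landmarks`) of distances in
#'   Angstrom.
#' @export
annotate_candidates <- function(model, chain = NULL, positions, landmarks) {
  stopifnot(inherits(model, "structure_model"))
  wanted <- unique(c(positions, landmarks))
  if (is.null(chain)) {
    for (ch in sort(unique(model$chain))) {
      if (all(wanted %in% model$resseq[model$chain == ch])) {
        chain <- ch
        break
      }
    }
    if (is.null(chain)) {
      stop("no chain contains all queried residues", call. = FALSE)
    }
  }
  out <- matrix(NA_real_, length(positions), length(landmarks),
                dimnames = list(positions, landmarks))
  for (i in seq_along(positions)) {
    for (j in seq_along(landmarks)) {
      out[i, j] <- min_residue_distance(model, chain, positions[i],
                                        landmarks[j])
    }
  }
  out
}
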