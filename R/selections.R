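# Atom selections and substructure annotations.

is_hydrogen <- function(atom) {
  elesy <- toupper(trimws(as.character(atom$elesy)))
  h <- elesy == "H"
  # fall back on the atom-name convention when the element column is blank
  blank <- is.na(elesy) | elesy == ""
  h[blank] <- grepl("^[0-9]*H", trimws(atom$elety[blank]))
  h
}

#' Select atoms of a structure
#'
#' The descriptor is either a character shorthand — an atom name such as
#' `"C5'"`, the element class `"heavy"` (all non-hydrogens), or `"all"` — or a
#' list with any of `elety` (atom name(s)), `resno` (residue numbers),
#' `heavy = TRUE`. List components are intersected.
#'
#' @param structure a structure object.
#' @param descriptor character shorthand or list, see Details.
#' @return an `atom_selection`: descriptor string, sorted unique atom indices
#'   and the matching xyz column indices.
#' @examples
#' \dontrun{select_atoms(s, "C5'"); select_atoms(s, list(heavy = TRUE, resno = 1:8))}
#' @export
select_atoms <- function(structure, descriptor) {
  if (inherits(structure, "ribo_trajectory")) structure <- structure$topology
  atom <- structure$atom
  if (is.character(descriptor) && length(descriptor) == 1) {
    desc_str <- descriptor
    idx <- switch(descriptor,
      all   = seq_len(nrow(atom)),
      heavy = which(!is_hydrogen(atom)),
      which(trimws(atom$elety) == descriptor)
    )
  } else if (is.list(descriptor)) {
    keep <- rep(TRUE, nrow(atom))
    if (!is.null(descriptor$elety))
      keep <- keep & trimws(atom$elety) %in% descriptor$elety
    if (!is.null(descriptor$resno))
      keep <- keep & atom$resno %in% descriptor$resno
    if (isTRUE(descriptor$heavy))
      keep <- keep & !is_hydrogen(atom)
    idx <- which(keep)
    desc_str <- paste(
      c(if (!is.null(descriptor$elety)) paste0("elety=", paste(descriptor$elety, collapse = "/")),
        if (!is.null(descriptor$resno)) sprintf("resno[%d]", length(descriptor$resno)),
        if (isTRUE(descriptor$heavy)) "heavy"),
      collapse = " & ")
  } else stopf("descriptor must be a string or a list")

  idx <- sort(unique(idx))
  if (length(idx) == 0)
    stopf("empty selection: descriptor '%s' matches no atoms",
          if (is.character(descriptor)) descriptor else desc_str)
  structure(
    list(descriptor = desc_str, atom = idx, xyz = xyz_index(idx)),
    class = "atom_selection"
  )
}

#' @export
print.atom_selection <- function(x, ...) {
  cat(sprintf("<atom selection> '%s': %d atoms\n", x$descriptor, length(x$atom)))
  invisible(x)
}

parse_range_list <- function(txt) {
  out <- integer(0)
  for (piece in strsplit(txt, ",")[[1]]) {
    piece <- trimws(piece)
    if (piece == "") next
    if (grepl("^[0-9]+\\s*-\\s*[0-9]+$", piece)) {
      ab <- as.integer(strsplit(piece, "-", fixed = TRUE)[[1]])
      out <- c(out, seq(ab[1], ab[2]))
    } else {
      v <- suppressWarnings(as.integer(piece))
      if (is.na(v)) stopf("malformed residue range '%s'", piece)
      out <- c(out, v)
    }
  }
  sort(unique(out))
}

#' Load a substructure annotation file
#'
#' The file maps region names to inclusive 1-based residue ranges, one region
#' per line, e.g. `P1: 1-8,92-99`. Lines starting with `#` and blank lines are
#' ignored. Regions may overlap (e.g. `whole` alongside `P3-L3`). Every
#' referenced residue must exist in `structure` (author `resno` numbering).
#'
#' @param path annotation file path.
#' @param structure a structure object used for validation.
#' @return a named list of sorted residue-number vectors
#'   (class `substructure_annotation`).
#' @export
load_annotation <- function(path, structure) {
  if (!file.exists(path)) stopf("no such file: %s", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  regions <- list()
  for (ln in lines) {
    parts <- strsplit(ln, ":", fixed = TRUE)[[1]]
    if (length(parts) != 2)
      stopf("malformed annotation line: '%s'", ln)
    nm <- trimws(parts[1])
    if (nm %in% names(regions)) stopf("duplicate region name '%s'", nm)
    regions[[nm]] <- parse_range_list(parts[2])
  }
  annotation(regions, structure)
}

#' Build a substructure annotation from a list
#'
#' @param regions named list of residue-number vectors (or range strings).
#' @param structure optional structure for validation.
#' @return a `substructure_annotation` object.
#' @export
annotation <- function(regions, structure = NULL) {
  stopifnot(is.list(regions), !is.null(names(regions)), all(names(regions) != ""))
  regions <- lapply(regions, function(r)
    if (is.character(r)) parse_range_list(r) else sort(unique(as.integer(r))))
  if (!is.null(structure)) {
    if (inherits(structure, "ribo_trajectory")) structure <- structure$topology
    known <- unique(structure$atom$resno)
    for (nm in names(regions)) {
      missing <- setdiff(regions[[nm]], known)
      if (length(missing) > 0)
        stopf("annotation region '%s' references residue(s) %s absent from structure",
              nm, paste(utils::head(missing, 3), collapse = ","))
    }
  }
  structure(regions, class = "substructure_annotation")
}

#' @export
print.substructure_annotation <- function(x, ...) {
  cat("<substructure annotation>\n")
  for (nm in names(x))
    cat(sprintf("  %-8s %d residues\n", nm, length(x[[nm]])))
  invisible(x)
}

# heavy atoms belonging to an annotated region
region_selection <- function(structure, annotation, region, heavy = TRUE) {
  if (!region %in% names(annotation))
    stopf("region '%s' absent from annotation (have: %s)",
          region, paste(names(annotation), collapse = ", "))
  select_atoms(structure, list(resno = annotation[[region]], heavy = heavy))
}
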