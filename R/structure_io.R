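# Structures, trajectories and their PDB round-trip.
#
# Atom records are held in a data frame following bio3d column names
# (eleno, elety, resid, chain, resno, insert, x, y, z, elesy) plus
# `res_index`, a 1-based sequential residue index assigned in order of first
# appearance of each (chain, resno, insert) triple. Author residue numbers
# (`resno`) are what annotation files and user-facing selections refer to,
# matching conventional nucleotide numbering (e.g. "U36").

new_structure <- function(atom) {
  required <- c("eleno", "elety", "resid", "chain", "resno", "insert",
                "x", "y", "z", "elesy")
  miss <- setdiff(required, names(atom))
  if (length(miss) > 0)
    stopf("atom table is missing column(s): %s", paste(miss, collapse = ", "))
  if (nrow(atom) == 0) stopf("structure has no atoms (empty model)")
  coords <- as.matrix(atom[, c("x", "y", "z")])
  if (!all(is.finite(coords))) stopf("structure contains non-finite coordinates")

  key <- paste(atom$chain, atom$resno, atom$insert, sep = "|")
  atom$res_index <- as.integer(factor(key, levels = unique(key)))

  # atom names must be unique within a residue
  dup <- duplicated(paste(key, atom$elety))
  if (any(dup))
    stopf("duplicate atom name '%s' in residue %s%s", atom$elety[dup][1],
          atom$resid[dup][1], atom$resno[dup][1])

  structure(
    list(atom = atom, xyz = mat2vec(coords)),
    class = "ribo_structure"
  )
}

#' Number of atoms, residues, frames
#'
#' @param x a structure or trajectory object.
#' @return integer count.
#' @export
n_atoms <- function(x) {
  if (inherits(x, "ribo_trajectory")) x <- x$topology
  nrow(x$atom)
}

#' @rdname n_atoms
#' @export
n_residues <- function(x) {
  if (inherits(x, "ribo_trajectory")) x <- x$topology
  max(x$atom$res_index)
}

#' @rdname n_atoms
#' @export
n_frames <- function(x) {
  stopifnot(inherits(x, "ribo_trajectory"))
  nrow(x$xyz)
}

#' @export
print.ribo_structure <- function(x, ...) {
  cat(sprintf("<structure> %d atoms, %d residues, chains: %s\n",
              n_atoms(x), n_residues(x),
              paste(unique(x$atom$chain), collapse = ",")))
  invisible(x)
}

#' @export
print.ribo_trajectory <- function(x, ...) {
  cat(sprintf("<trajectory> %d frames x %d atoms (%d residues)\n",
              n_frames(x), n_atoms(x), n_residues(x)))
  invisible(x)
}

# validate fixed-width numeric fields of coordinate records before handing
# the file to the parser, so format errors can name the offending line
check_pdb_records <- function(lines) {
  rec <- grepl("^(ATOM  |HETATM)", lines)
  bad_len <- rec & nchar(lines) < 54
  if (any(bad_len))
    stopf("unparseable PDB record at line %d (truncated coordinate fields)",
          which(bad_len)[1])
  for (i in which(rec)) {
    xyz <- suppressWarnings(as.numeric(c(substr(lines[i], 31, 38),
                                         substr(lines[i], 39, 46),
                                         substr(lines[i], 47, 54))))
    if (any(is.na(xyz)))
      stopf("unparseable PDB record at line %d (non-numeric coordinates)", i)
  }
  invisible(sum(rec))
}

#' Read a PDB structure (first model only)
#'
#' Reads all ATOM/HETATM records of the first model into a structure object.
#' Alternate locations other than blank or "A" are discarded (single-conformer
#' convention); insertion codes are preserved as part of residue identity.
#' Multi-model files are deliberately NOT read as trajectories here — use
#' [read_multimodel_trajectory()] for that.
#'
#' @param path PDB file path.
#' @return a structure object (atom table + coordinates in Angstrom).
#' @seealso [write_structure_pdb()], [read_multimodel_trajectory()]
#' @export
read_pdb <- function(path) {
  if (!file.exists(path)) stopf("no such file: %s", path)
  lines <- readLines(path, warn = FALSE)
  if (check_pdb_records(lines) == 0)
    stopf("empty model: no ATOM/HETATM records in %s", path)
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  atom <- pdb$atom
  xyz1 <- if (is.matrix(pdb$xyz)) pdb$xyz[1, ] else as.numeric(pdb$xyz)
  atom$x <- xyz1[seq(1, length(xyz1), 3)]
  atom$y <- xyz1[seq(2, length(xyz1), 3)]
  atom$z <- xyz1[seq(3, length(xyz1), 3)]

  keep <- is.na(atom$alt) | atom$alt %in% c("", "A")
  atom <- atom[keep, , drop = FALSE]
  atom$insert[is.na(atom$insert)] <- ""
  atom$chain[is.na(atom$chain)] <- " "

  # ATOM records must be residue-ordered within each chain (HETATM appended
  # blocks such as ions/waters are exempt)
  at <- atom[atom$type == "ATOM", , drop = FALSE]
  if (nrow(at) > 1) {
    for (ch in unique(at$chain)) {
      r <- at$resno[at$chain == ch]
      if (any(diff(r) < 0))
        stopf("residue numbering not ordered within chain '%s'", ch)
    }
  }
  new_structure(atom)
}

# minimal bio3d 'pdb' object for write.pdb (which requires one when the
# coordinates span multiple models)
as_bio3d_pdb <- function(structure) {
  a <- structure$atom
  n <- nrow(a)
  atom <- data.frame(
    type = a$type %||% rep("ATOM", n), eleno = a$eleno, elety = a$elety,
    alt = rep(as.character(NA), n), resid = a$resid, chain = a$chain,
    resno = a$resno, insert = ifelse(a$insert == "", as.character(NA), a$insert),
    x = a$x, y = a$y, z = a$z, o = rep(1, n), b = rep(0, n),
    segid = rep(as.character(NA), n), elesy = a$elesy,
    charge = rep(as.character(NA), n), stringsAsFactors = FALSE)
  structure(list(atom = atom, xyz = bio3d::as.xyz(matrix(structure$xyz, nrow = 1)),
                 calpha = rep(FALSE, n)),
            class = c("pdb", "sse"))
}

#' Write a structure as a single-model PDB file
#'
#' @param structure a structure object.
#' @param path output file path.
#' @return invisibly, `path`.
#' @export
write_structure_pdb <- function(structure, path) {
  bio3d::write.pdb(pdb = as_bio3d_pdb(structure), file = path)
  invisible(path)
}

new_trajectory <- function(topology, xyz, frame_labels = NULL) {
  stopifnot(inherits(topology, "ribo_structure"))
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1)
  if (ncol(xyz) != 3L * n_atoms(topology))
    stopf("coordinate width %d does not match topology (%d atoms)",
          ncol(xyz), n_atoms(topology))
  if (nrow(xyz) < 1) stopf("trajectory must have at least one frame")
  if (!all(is.finite(xyz))) stopf("trajectory contains non-finite coordinates")
  structure(
    list(topology = topology, xyz = xyz,
         frame_labels = frame_labels %||% seq_len(nrow(xyz))),
    class = "ribo_trajectory"
  )
}

#' Read a multi-model PDB file as a trajectory
#'
#' Every MODEL block must contain exactly the same atoms, in the same order,
#' as `topology`; a mismatch is reported with the offending model number.
#' A file without MODEL records is read as a single-frame trajectory.
#'
#' @param path multi-model PDB file.
#' @param topology a structure object giving atom identity and order.
#' @return a trajectory object (frames x 3*n_atoms coordinate matrix).
#' @export
read_multimodel_trajectory <- function(path, topology) {
  if (!file.exists(path)) stopf("no such file: %s", path)
  lines <- readLines(path, warn = FALSE)
  check_pdb_records(lines)
  is_rec <- grepl("^(ATOM  |HETATM)", lines)
  model_starts <- grep("^MODEL", lines)

  nat <- n_atoms(topology)
  if (length(model_starts) == 0) {
    counts <- sum(is_rec)
    if (counts != nat)
      stopf("topology mismatch: file has %d atoms, topology has %d", counts, nat)
  } else {
    model_ends <- grep("^ENDMDL", lines)
    if (length(model_ends) != length(model_starts))
      stopf("unbalanced MODEL/ENDMDL records in %s", path)
    for (m in seq_along(model_starts)) {
      cnt <- sum(is_rec[model_starts[m]:model_ends[m]])
      if (cnt != nat)
        stopf("topology mismatch in model %d: %d atoms, expected %d", m, cnt, nat)
    }
  }

  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  xyz <- pdb$xyz
  if (is.null(dim(xyz))) xyz <- matrix(as.numeric(xyz), nrow = 1)
  if (!identical(as.character(pdb$atom$elety), as.character(topology$atom$elety)))
    stopf("topology mismatch: atom names differ from topology")
  new_trajectory(topology, unclass(xyz)[, , drop = FALSE])
}

#' Write a trajectory as a multi-model PDB file
#'
#' @param trajectory a trajectory object.
#' @param path output file path.
#' @return invisibly, `path`.
#' @export
write_trajectory_pdb <- function(trajectory, path) {
  bio3d::write.pdb(pdb = as_bio3d_pdb(trajectory$topology),
                   xyz = bio3d::as.xyz(trajectory$xyz), file = path)
  invisible(path)
}

#' Concatenate trajectories sharing a topology
#'
#' Frames are appended in argument order; the result has as many frames as
#' the inputs combined. Used to pool independent replicas before computing
#' occupancies or contact masks.
#'
#' @param ... two or more trajectory objects with identical topologies.
#' @return a trajectory object.
#' @export
concat_trajectories <- function(...) {
  trjs <- list(...)
  if (length(trjs) == 1 && is.list(trjs[[1]]) && !inherits(trjs[[1]], "ribo_trajectory"))
    trjs <- trjs[[1]]
  stopifnot(length(trjs) >= 1)
  ref <- trjs[[1]]
  for (t in trjs[-1]) {
    if (n_atoms(t) != n_atoms(ref) ||
        !identical(as.character(t$topology$atom$elety),
                   as.character(ref$topology$atom$elety)))
      stopf("cannot concatenate: topologies differ")
  }
  new_trajectory(ref$topology, do.call(rbind, lapply(trjs, `[[`, "xyz")))
}

#' Build a trajectory from an in-memory coordinate matrix
#'
#' Adapter hook for externally decoded trajectory formats: any reader that
#' produces frames in the topology's atom order can feed the pipeline here.
#'
#' @param topology a structure object.
#' @param xyz numeric matrix, one frame per row, columns (x1,y1,z1,x2,...).
#' @param frame_labels optional integer frame labels.
#' @return a trajectory object.
#' @export
trajectory_from_xyz <- function(topology, xyz, frame_labels = NULL) {
  new_trajectory(topology, xyz, frame_labels)
}
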