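# Persistent residue-residue contact mask used to filter correlation networks.

#' Persistent contact mask between residues
#'
#' A residue pair is "in contact" in a frame when the minimum distance between
#' their selected atoms is strictly below `cutoff`; the mask is TRUE for pairs
#' in contact in at least a `persistence` fraction of frames (>=, so exactly
#' 75% of frames passes at the default). The diagonal is TRUE by definition.
#'
#' @param trajectory a trajectory object.
#' @param selection atoms used for the distance test: `"heavy"` (default,
#'   minimum heavy-atom distance) or any descriptor accepted by
#'   [select_atoms()] (e.g. `"C5'"` for a backbone-only alternative).
#' @param cutoff contact distance in Angstrom (default 4.5).
#' @param persistence minimum in-contact fraction of frames (default 0.75).
#' @return a `contact_mask`: logical matrix over residues (labelled by
#'   residue number), the in-contact fraction matrix, and the parameters.
#' @export
contact_mask <- function(trajectory, selection = "heavy",
                         cutoff = 4.5, persistence = 0.75) {
  sel <- if (inherits(selection, "atom_selection")) selection
         else select_atoms(trajectory$topology, selection)
  atom <- trajectory$topology$atom
  res_of <- atom$res_index[sel$atom]
  nres <- n_residues(trajectory)
  nf <- n_frames(trajectory)

  # residue membership indicator (nres x natoms-in-selection)
  Rm <- matrix(0, nres, length(sel$atom))
  Rm[cbind(res_of, seq_along(sel$atom))] <- 1

  cut2 <- cutoff^2
  counts <- matrix(0, nres, nres)
  for (f in seq_len(nf)) {
    m <- vec2mat(trajectory$xyz[f, ])[sel$atom, , drop = FALSE]
    B <- pairdist2(m) < cut2
    touch <- Rm %*% B %*% t(Rm)      # atom-pair contacts per residue pair
    counts <- counts + (touch > 0)
  }

  fraction <- counts / nf
  mask <- fraction >= persistence
  diag(mask) <- TRUE
  labels <- as.character(atom$resno[match(seq_len(nres), atom$res_index)])
  dimnames(mask) <- dimnames(fraction) <- list(labels, labels)
  structure(
    list(mask = mask, fraction = fraction,
         cutoff = cutoff, persistence = persistence,
         selection = sel$descriptor),
    class = "contact_mask"
  )
}

#' @export
print.contact_mask <- function(x, ...) {
  n <- nrow(x$mask)
  cat(sprintf("<contact mask> %d residues, %d contact pairs (cutoff %.1f A, persistence %.0f%%)\n",
              n, (sum(x$mask) - n) / 2, x$cutoff, 100 * x$persistence))
  invisible(x)
}
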