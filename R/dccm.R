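# Dynamic cross-correlation matrices and replica consensus.

#' Compute a dynamic cross-correlation matrix
#'
#' Frames are superposed onto the initial structure (first frame) over the
#' selection, then for each pair of selected atoms
#' `C_ij = <dr_i . dr_j> / sqrt(<|dr_i|^2><|dr_j|^2>)` with `dr` the
#' displacement from the time-mean position. Entries lie in [-1, 1] with unit
#' diagonal. One atom per residue (conventionally C5' for nucleic acids)
#' makes this a residue-residue correlation matrix.
#'
#' @param trajectory a trajectory object with >= 2 frames.
#' @param selection an `atom_selection`, one atom per residue recommended.
#' @param reference superposition reference: `"initial"` (default, first
#'   frame) or `"mean"`.
#' @return a `dccm_mat`: symmetric correlation matrix with residue-number
#'   labels.
#' @export
compute_dccm <- function(trajectory, selection, reference = c("initial", "mean")) {
  reference <- match.arg(reference)
  if (n_frames(trajectory) < 2) stopf("DCCM requires at least 2 frames")
  X <- trajectory$xyz[, selection$xyz, drop = FALSE]
  nsel <- length(selection$atom)

  ref <- if (reference == "initial") X[1, ] else colMeans(X)
  refm <- vec2mat(ref)
  for (f in seq_len(nrow(X)))
    X[f, ] <- mat2vec(kabsch_superpose(vec2mat(X[f, ]), refm)$xyz)

  Xc <- sweep(X, 2, colMeans(X))
  A <- crossprod(Xc) / nrow(Xc)
  ix <- seq(1, 3 * nsel, 3)
  dot <- A[ix, ix] + A[ix + 1, ix + 1] + A[ix + 2, ix + 2]
  v <- diag(dot)
  if (any(v <= 1e-14)) {
    bad <- trajectory$topology$atom$resno[selection$atom][which(v <= 1e-14)[1]]
    stopf("undefined correlation: node (residue %s) has zero positional variance", bad)
  }
  C <- dot / sqrt(outer(v, v))
  C <- (C + t(C)) / 2
  C[C > 1] <- 1; C[C < -1] <- -1
  diag(C) <- 1
  labels <- as.character(trajectory$topology$atom$resno[selection$atom])
  dimnames(C) <- list(labels, labels)
  structure(C, class = c("dccm_mat", "matrix"))
}

#' Consensus of replica DCCMs
#'
#' The default consensus is the element-wise mean of the replica matrices.
#' The alternative `"cutoff"` mode keeps an entry only when `|C| >= cutoff`
#' in every replica (and then averages), setting it to 0 otherwise — a
#' stricter consensus that only retains couplings reproduced by all replicas.
#'
#' @param matrices list of `dccm_mat` objects with identical node sets.
#' @param mode `"mean"` (default) or `"cutoff"`.
#' @param cutoff minimum `|C|` required in all replicas for `"cutoff"` mode.
#' @return a `dccm_mat`.
#' @export
consensus_dccm <- function(matrices, mode = c("mean", "cutoff"), cutoff = 0.6) {
  mode <- match.arg(mode)
  stopifnot(length(matrices) >= 1)
  d <- dim(matrices[[1]])
  lab <- dimnames(matrices[[1]])
  for (m in matrices) {
    if (!identical(dim(m), d) || !identical(dimnames(m), lab))
      stopf("DCCM shape/label mismatch across replicas")
  }
  arr <- simplify2array(lapply(matrices, unclass))
  M <- apply(arr, c(1, 2), mean)
  if (mode == "cutoff") {
    keep <- apply(abs(arr) >= cutoff, c(1, 2), all)
    M[!keep] <- 0
  }
  diag(M) <- 1
  dimnames(M) <- lab
  structure(M, class = c("dccm_mat", "matrix"))
}
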