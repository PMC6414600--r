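# Least-squares (Kabsch) superposition.

#' Kabsch superposition of one coordinate set onto another
#'
#' Finds the proper rotation (determinant +1) and translation minimising the
#' RMSD between `mobile` and `reference` over `fit_indices`, and applies the
#' transform to ALL atoms of `mobile`.
#'
#' @param mobile,reference coordinate sets: n x 3 matrices or xyz vectors of
#'   equal length.
#' @param fit_indices atom indices used for the fit (default: all atoms).
#' @return list with `xyz` (transformed n x 3 coordinates), `rmsd` (fit RMSD,
#'   Angstrom), `rotation` (3 x 3), `translation` (length-3).
#' @export
kabsch_superpose <- function(mobile, reference, fit_indices = NULL) {
  P <- if (is.matrix(mobile)) mobile else vec2mat(mobile)
  Q <- if (is.matrix(reference)) reference else vec2mat(reference)
  if (nrow(P) != nrow(Q)) stopf("coordinate sets differ in atom count")
  fit <- fit_indices %||% seq_len(nrow(P))
  if (length(fit) < 3) stopf("degenerate fit: need at least 3 fit points")

  pc <- colMeans(P[fit, , drop = FALSE])
  qc <- colMeans(Q[fit, , drop = FALSE])
  Pf <- sweep(P[fit, , drop = FALSE], 2, pc)
  Qf <- sweep(Q[fit, , drop = FALSE], 2, qc)

  # collinear fit points leave the rotation under-determined
  sv_fit <- svd(Pf, nu = 0, nv = 0)$d
  if (sv_fit[2] < 1e-8 * max(sv_fit[1], 1))
    stopf("degenerate fit: fit points are (near-)collinear")

  H <- crossprod(Pf, Qf)
  s <- svd(H)
  d <- sign(det(s$u) * det(s$v))
  R <- s$u %*% diag(c(1, 1, d)) %*% t(s$v)

  moved <- sweep(P, 2, pc) %*% R
  moved <- sweep(moved, 2, qc, "+")
  rmsd <- sqrt(mean(rowSums((moved[fit, , drop = FALSE] -
                             Q[fit, , drop = FALSE])^2)))
  list(xyz = moved, rmsd = rmsd, rotation = R, translation = qc - pc %*% R)
}

# RMSD between two coordinate sets over given atoms (no fitting)
coord_rmsd <- function(a, b, idx = NULL) {
  A <- if (is.matrix(a)) a else vec2mat(a)
  B <- if (is.matrix(b)) b else vec2mat(b)
  idx <- idx %||% seq_len(nrow(A))
  sqrt(mean(rowSums((A[idx, , drop = FALSE] - B[idx, , drop = FALSE])^2)))
}

# Superpose every trajectory frame onto reference coordinates over the fit
# atoms; returns a new frames x 3n matrix.
superpose_frames <- function(xyz, ref_xyz, fit_atoms) {
  refm <- if (is.matrix(ref_xyz)) ref_xyz else vec2mat(ref_xyz)
  out <- xyz
  for (f in seq_len(nrow(xyz))) {
    out[f, ] <- mat2vec(kabsch_superpose(vec2mat(xyz[f, ]), refm,
                                         fit_indices = fit_atoms)$xyz)
  }
  out
}

#' Superpose a trajectory onto a reference
#'
#' @param trajectory a trajectory object.
#' @param reference a structure, a frame index, or an xyz vector; default the
#'   first frame.
#' @param fit_selection an `atom_selection` (default: all atoms).
#' @return a trajectory object with superposed frames.
#' @export
superpose_trajectory <- function(trajectory, reference = 1L, fit_selection = NULL) {
  ref_xyz <- resolve_reference(trajectory, reference)
  fit <- if (is.null(fit_selection)) seq_len(n_atoms(trajectory)) else fit_selection$atom
  new_trajectory(trajectory$topology,
                 superpose_frames(trajectory$xyz, ref_xyz, fit),
                 trajectory$frame_labels)
}

resolve_reference <- function(trajectory, reference) {
  if (inherits(reference, "ribo_structure")) {
    if (n_atoms(reference) != n_atoms(trajectory))
      stopf("reference structure does not match trajectory topology")
    reference$xyz
  } else if (is.numeric(reference) && length(reference) == 1) {
    trajectory$xyz[as.integer(reference), ]
  } else if (is.numeric(reference) && length(reference) == 3L * n_atoms(trajectory)) {
    as.numeric(reference)
  } else stopf("cannot interpret RMSD reference")
}
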