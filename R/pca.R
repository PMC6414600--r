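# Principal component analysis of selection coordinates (typically the C5'
# backbone atoms): 3N x 3N positional covariance after least-squares
# superposition onto the average structure.

#' Fit a PCA model to a trajectory
#'
#' Frames are superposed onto the average structure over the selection
#' (rotational and translational motion removed), the 3N x 3N covariance
#' matrix of the selected coordinates is formed with the population (1/n)
#' denominator, and eigendecomposed. Eigenvector signs are fixed by making
#' each vector's largest-magnitude component positive so results are
#' reproducible across platforms.
#'
#' @param trajectory a trajectory object with >= 2 frames.
#' @param selection an `atom_selection` (e.g. `select_atoms(s, "C5'")`).
#' @param denominator `"population"` (default, divide by n) or `"sample"`
#'   (divide by n-1).
#' @return a `pca_model`: `mean` (3N xyz of the average structure),
#'   `values` (eigenvalues, Angstrom^2, non-increasing), `vectors`
#'   (orthonormal columns), `fractional` (variance fractions summing to 1),
#'   `labels` (residue numbers of the selected atoms).
#' @export
fit_pca <- function(trajectory, selection,
                    denominator = c("population", "sample")) {
  denominator <- match.arg(denominator)
  if (n_frames(trajectory) < 2) stopf("PCA requires at least 2 frames")
  X <- trajectory$xyz[, selection$xyz, drop = FALSE]
  if (max(abs(sweep(X, 2, X[1, ]))) < 1e-12)
    stopf("zero variance: all frames are identical over the selection")

  # single fit-to-mean pass, then recompute the mean (same convention as RMSF)
  sub <- X
  nsel <- length(selection$atom)
  mean0 <- colMeans(sub)
  for (f in seq_len(nrow(sub)))
    sub[f, ] <- mat2vec(kabsch_superpose(vec2mat(sub[f, ]), vec2mat(mean0))$xyz)
  mu <- colMeans(sub)

  Xc <- sweep(sub, 2, mu)
  nden <- if (denominator == "population") nrow(Xc) else nrow(Xc) - 1L
  C <- crossprod(Xc) / nden
  e <- eigen(C, symmetric = TRUE)
  vals <- e$values
  vals[vals < 0 & vals > -1e-9] <- 0
  if (any(vals < 0)) stopf("covariance eigenvalues below tolerance")
  vecs <- e$vectors
  for (k in seq_len(ncol(vecs))) {
    j <- which.max(abs(vecs[, k]))
    if (vecs[j, k] < 0) vecs[, k] <- -vecs[, k]
  }

  structure(
    list(mean = mu, values = vals, vectors = vecs,
         fractional = vals / sum(vals),
         selection = selection,
         labels = trajectory$topology$atom$resno[selection$atom]),
    class = "pca_model"
  )
}

#' @export
print.pca_model <- function(x, ...) {
  k <- min(3, length(x$values))
  cat(sprintf("<pca model> %d coordinates; PC1-%d variance: %s\n",
              length(x$mean), k,
              paste(sprintf("%.1f%%", 100 * x$fractional[1:k]), collapse = ", ")))
  invisible(x)
}

#' Per-atom RMSF contributed by selected principal components
#'
#' `RMSF_i = sqrt( sum_k lambda_k * |v_k(atom i)|^2 )` over the chosen PCs.
#' With all PCs included this equals the total RMSF about the mean structure.
#'
#' @param model a `pca_model`.
#' @param pcs integer indices of the components to include.
#' @return numeric vector, one value per selected atom (Angstrom).
#' @export
pc_rmsf <- function(model, pcs) {
  if (any(pcs < 1 | pcs > length(model$values)))
    stopf("PC index out of range (model has %d components)", length(model$values))
  natom <- length(model$mean) / 3
  acc <- numeric(natom)
  for (k in pcs) {
    v <- model$vectors[, k]
    acc <- acc + model$values[k] *
      (v[seq(1, 3 * natom, 3)]^2 + v[seq(2, 3 * natom, 3)]^2 + v[seq(3, 3 * natom, 3)]^2)
  }
  sqrt(acc)
}

#' Project a trajectory onto principal components
#'
#' Each frame is superposed onto the model's mean structure over the
#' selection, centred, and dotted with the chosen eigenvectors.
#'
#' @param trajectory a trajectory object matching the model's selection.
#' @param model a `pca_model`.
#' @param pcs component indices (default 1:2, the PC1-PC2 subspace).
#' @return a `pc_projection`: n_frames x length(pcs) score matrix (Angstrom).
#' @export
project <- function(trajectory, model, pcs = 1:2) {
  sel <- model$selection
  if (3L * length(sel$atom) != length(model$mean) ||
      max(sel$atom) > n_atoms(trajectory))
    stopf("trajectory does not match the model selection")
  X <- trajectory$xyz[, sel$xyz, drop = FALSE]
  mum <- vec2mat(model$mean)
  for (f in seq_len(nrow(X)))
    X[f, ] <- mat2vec(kabsch_superpose(vec2mat(X[f, ]), mum)$xyz)
  scores <- sweep(X, 2, model$mean) %*% model$vectors[, pcs, drop = FALSE]
  colnames(scores) <- paste0("PC", pcs)
  structure(scores, class = c("pc_projection", "matrix"))
}

#' Complete-linkage clustering of the PC1-PC2 subspace
#'
#' Agglomerative hierarchical clustering (`hclust`, complete linkage) on the
#' Euclidean distance between frame scores in a 2-PC subspace, cut at `k`
#' clusters. This is the conventional way of partitioning the conformations
#' explored along the two dominant modes.
#'
#' @param projection a `pc_projection` with exactly 2 columns.
#' @param k number of clusters (1 <= k <= n_frames).
#' @return integer vector of per-frame cluster labels.
#' @export
cluster_pc_subspace <- function(projection, k) {
  m <- unclass(projection)
  if (ncol(m) != 2) stopf("clustering expects exactly 2 PCs")
  if (k < 1 || k > nrow(m)) stopf("k must be between 1 and n_frames")
  hc <- stats::hclust(stats::dist(m), method = "complete")
  as.integer(stats::cutree(hc, k = k))
}

#' Extreme-projection structures along a principal component
#'
#' Emits interpolated selection coordinates between the minimum and maximum
#' observed projection along one PC, as a trajectory writable with
#' [write_trajectory_pdb()] (the usual way to visualise a mode).
#'
#' @param model a `pca_model`.
#' @param trajectory the fitting trajectory (used for the projection range).
#' @param pc component index.
#' @param n_steps number of interpolation steps (default 5).
#' @return a trajectory over the selection atoms only.
#' @export
pc_extremes <- function(model, trajectory, pc = 1, n_steps = 5) {
  sc <- project(trajectory, model, pcs = pc)
  rng <- range(sc[, 1])
  steps <- seq(rng[1], rng[2], length.out = n_steps)
  xyz <- t(vapply(steps, function(s) model$mean + s * model$vectors[, pc],
                  numeric(length(model$mean))))
  topo_sub <- subset_structure(trajectory$topology, model$selection$atom)
  new_trajectory(topo_sub, xyz)
}

# structure restricted to a set of atoms (keeps residue identity)
subset_structure <- function(structure, atom_idx) {
  new_structure(structure$atom[atom_idx, , drop = FALSE])
}
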