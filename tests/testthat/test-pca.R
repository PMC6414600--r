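mode_spec <- function(variances, n_res = 20, n_frames = 2000, seed = 101) {
  synthetic_spec(n_residues = n_res, n_frames = n_frames,
                 modes = variances, seed = seed)
}

test_that("identical frames are rejected as zero-variance input", {
  spec <- synthetic_spec(n_residues = 6, n_frames = 1, seed = 1)
  ref <- make_reference(spec)
  trj <- trajectory_from_xyz(ref, matrix(ref$xyz, 4, length(ref$xyz),
                                         byrow = TRUE))
  sel <- select_atoms(ref, "C5'")
  expect_error(fit_pca(trj, sel), "zero variance")
})

test_that("a single planted mode is recovered as PC1 with all the variance", {
  spec <- mode_spec(2.0, n_frames = 500, seed = 31)
  ref <- make_reference(spec)
  trj <- make_trajectory(ref, spec)
  sel <- select_atoms(ref, "C5'")
  model <- fit_pca(trj, sel)
  expect_equal(model$fractional[1], 1, tolerance = 1e-9)
  # eigenvector parallel to the planted direction
  set.seed(spec$seed)
  U <- ribonet:::make_mode_directions(
    as.matrix(ref$atom[sel$atom, c("x", "y", "z")]), 1)
  expect_gt(abs(sum(model$vectors[, 1] * U[, 1])), 0.999)
})

test_that("a planted 4:1 two-mode split is recovered in the variance fractions", {
  spec <- mode_spec(c(0.4, 0.1), n_frames = 4000, seed = 32)
  trj <- make_trajectory(make_reference(spec), spec)
  sel <- select_atoms(trj$topology, "C5'")
  model <- fit_pca(trj, sel)
  expect_lt(abs(model$fractional[1] - 0.8), 0.03)
  expect_lt(abs(model$fractional[2] - 0.2), 0.03)
  expect_equal(sum(model$fractional), 1, tolerance = 1e-9)
})

test_that("eigenvalues are ordered, eigenvectors orthonormal, trace conserved", {
  spec <- synthetic_spec(n_residues = 12, n_frames = 300, seed = 41)
  trj <- make_trajectory(make_reference(spec), spec)
  sel <- select_atoms(trj$topology, "C5'")
  model <- fit_pca(trj, sel)
  expect_true(all(diff(model$values) <= 1e-12))
  expect_true(all(model$values >= -1e-9))
  G <- crossprod(model$vectors)
  expect_lt(max(abs(G - diag(nrow(G)))), 1e-8)

  # trace conservation: sum of eigenvalues = total positional variance of the
  # superposed selection coordinates (same single fit-to-mean pass)
  X <- trj$xyz[, sel$xyz, drop = FALSE]
  X1 <- ribonet:::superpose_frames(X, colMeans(X), seq_along(sel$atom))
  total <- sum(colMeans(sweep(X1, 2, colMeans(X1))^2))
  expect_equal(sum(model$values), total, tolerance = 1e-9)
})

test_that("PCA agrees with an independent implementation on variance fractions", {
  spec <- synthetic_spec(n_residues = 14, n_frames = 250, seed = 42)
  trj <- make_trajectory(make_reference(spec), spec)
  sel <- select_atoms(trj$topology, "C5'")
  model <- fit_pca(trj, sel)
  # bio3d::pca.xyz on identically superposed coordinates (fractional variances
  # are denominator-convention free)
  X <- trj$xyz[, sel$xyz, drop = FALSE]
  mean0 <- colMeans(X)
  X1 <- ribonet:::superpose_frames(X, mean0, seq_along(sel$atom))
  X2 <- ribonet:::superpose_frames(X, colMeans(X1), seq_along(sel$atom))
  ext <- bio3d::pca.xyz(X2)
  k <- 5
  expect_equal(model$fractional[1:k], (ext$L / sum(ext$L))[1:k],
               tolerance = 1e-6)
})

test_that("pc_rmsf reconstructs total and partial fluctuation profiles", {
  spec <- mode_spec(c(0.4, 0.2, 0.1), n_frames = 800, seed = 51)
  trj <- make_trajectory(make_reference(spec), spec)
  sel <- select_atoms(trj$topology, "C5'")
  model <- fit_pca(trj, sel)
  all_pc <- pc_rmsf(model, seq_along(model$values))

  # completeness: all PCs give the total RMSF about the PCA mean
  X <- trj$xyz[, sel$xyz, drop = FALSE]
  mum <- ribonet:::vec2mat(model$mean)
  for (f in seq_len(nrow(X)))
    X[f, ] <- ribonet:::mat2vec(kabsch_superpose(
      ribonet:::vec2mat(X[f, ]), mum)$xyz)
  msd <- colMeans(sweep(X, 2, colMeans(X))^2)
  total <- sqrt(msd[seq(1, length(msd), 3)] + msd[seq(2, length(msd), 3)] +
                msd[seq(3, length(msd), 3)])
  expect_equal(all_pc, unname(total), tolerance = 1e-6)

  # PCs 1-3 equal the RMSF of the trajectory reconstructed from those PCs
  scores <- project(trj, model, pcs = 1:3)
  recon <- unclass(scores) %*% t(model$vectors[, 1:3])
  msd_r <- colMeans(sweep(recon, 2, colMeans(recon))^2)
  rec_rmsf <- sqrt(msd_r[seq(1, length(msd_r), 3)] +
                   msd_r[seq(2, length(msd_r), 3)] +
                   msd_r[seq(3, length(msd_r), 3)])
  expect_equal(pc_rmsf(model, 1:3), unname(rec_rmsf), tolerance = 1e-6)

  expect_error(pc_rmsf(model, 10^6), "out of range")
})

test_that("projections behave linearly with known scores", {
  spec <- mode_spec(c(0.5, 0.2), n_frames = 600, seed = 61)
  ref <- make_reference(spec)
  trj <- make_trajectory(ref, spec)
  sel <- select_atoms(ref, "C5'")
  model <- fit_pca(trj, sel)

  # the mean structure projects to zero
  mean_frame <- trj$xyz[1, , drop = FALSE] * 0
  mean_frame[1, sel$xyz] <- model$mean
  mean_frame[1, -sel$xyz] <- colMeans(trj$xyz)[-sel$xyz]
  sc0 <- project(trajectory_from_xyz(ref, mean_frame), model, pcs = 1:2)
  expect_equal(as.numeric(sc0), c(0, 0), tolerance = 1e-8)

  # per-PC score variance equals the eigenvalue (population convention)
  sc <- project(trj, model, pcs = 1:3)
  vpop <- function(v) mean(v^2) - mean(v)^2
  expect_equal(apply(unclass(sc), 2, vpop), model$values[1:3],
               tolerance = 1e-6, ignore_attr = TRUE)
  # score columns are centred
  expect_lt(max(abs(colMeans(unclass(sc)))), 1e-6 * sqrt(model$values[1]))

  # displacing every frame by +c along eigenvector 1 shifts PC1 scores by c
  shift <- 0.9
  xyz2 <- trj$xyz
  xyz2[, sel$xyz] <- xyz2[, sel$xyz] +
    matrix(shift * model$vectors[, 1], nrow(xyz2), length(model$mean),
           byrow = TRUE)
  sc2 <- project(trajectory_from_xyz(ref, xyz2), model, pcs = 1)
  expect_equal(as.numeric(sc2), as.numeric(sc[, 1]) + shift, tolerance = 1e-6)
})

test_that("PCA is invariant to a global rigid motion applied to all frames", {
  spec <- synthetic_spec(n_residues = 10, n_frames = 200, seed = 71)
  trj <- make_trajectory(make_reference(spec), spec)
  sel <- select_atoms(trj$topology, "C5'")
  m1 <- fit_pca(trj, sel)
  # one common rotation + translation for every frame
  set.seed(3)
  Q <- qr.Q(qr(matrix(rnorm(9), 3)))
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  shift <- c(12, -7, 30)
  xyz <- t(apply(trj$xyz, 1, function(v)
    ribonet:::mat2vec(sweep(ribonet:::vec2mat(v) %*% Q, 2, shift, "+"))))
  m2 <- fit_pca(trajectory_from_xyz(trj$topology, xyz), sel)
  expect_equal(m1$values, m2$values, tolerance = 1e-9)
  expect_equal(m1$fractional, m2$fractional, tolerance = 1e-9)
})

test_that("complete-linkage clustering in the PC1-PC2 plane is exact on blobs", {
  set.seed(81)
  blob1 <- cbind(rnorm(30, 0, 0.5), rnorm(30, 0, 0.5))
  blob2 <- cbind(rnorm(30, 10, 0.5), rnorm(30, 10, 0.5))
  proj <- structure(rbind(blob1, blob2), class = c("pc_projection", "matrix"))
  labels <- cluster_pc_subspace(proj, k = 2)
  expect_equal(length(unique(labels[1:30])), 1)
  expect_equal(length(unique(labels[31:60])), 1)
  expect_true(labels[1] != labels[31])

  # k = n gives singletons; duplicated frames always share a label
  small <- structure(cbind(c(0, 1, 2), c(0, 1, 2)),
                     class = c("pc_projection", "matrix"))
  expect_equal(sort(cluster_pc_subspace(small, 3)), 1:3)
  dup <- structure(cbind(c(0, 5, 0, 9), c(0, 5, 0, 9)),
                   class = c("pc_projection", "matrix"))
  lab <- cluster_pc_subspace(dup, 3)
  expect_equal(lab[1], lab[3])
  expect_error(cluster_pc_subspace(small, 0), "between 1 and")
  expect_error(cluster_pc_subspace(small, 9), "between 1 and")
})

test_that("Frobenius error of the fitted covariance shrinks with frame count", {
  errs <- vapply(c(100, 1000), function(nf) {
    spec <- synthetic_spec(n_residues = 8, n_frames = nf,
      correlation_blocks = list(list(residues = 4:6, rho = 0.6)), seed = 91)
    trj <- make_trajectory(make_reference(spec), spec)
    sel <- select_atoms(trj$topology, "C5'")
    C <- compute_dccm(trj, sel)
    target <- diag(8)
    target[4:6, 4:6] <- 0.6; diag(target) <- 1
    sqrt(sum((unclass(C) - target)^2))
  }, numeric(1))
  expect_lt(errs[2], errs[1])
})

test_that("extreme-projection structures span the observed PC range", {
  spec <- mode_spec(c(0.4), n_frames = 300, seed = 95)
  trj <- make_trajectory(make_reference(spec), spec)
  sel <- select_atoms(trj$topology, "C5'")
  model <- fit_pca(trj, sel)
  ext <- pc_extremes(model, trj, pc = 1, n_steps = 5)
  expect_equal(n_frames(ext), 5)
  expect_equal(n_atoms(ext), length(sel$atom))
  # end frames sit at the observed score extremes along the eigenvector
  sc <- project(trj, model, pcs = 1)
  span <- diff(range(sc[, 1]))
  expect_equal(sqrt(sum((ext$xyz[5, ] - ext$xyz[1, ])^2)), span,
               tolerance = 1e-9)
})
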