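# donor D at origin with H at (1,0,0); acceptor placed to realise a chosen
# D-H-A angle and D-A distance
place_acceptor <- function(dha_deg, reach) {
  phi <- (180 - dha_deg) * pi / 180
  c(1, 0, 0) + reach * c(cos(phi), sin(phi), 0)
}

# 2-residue structure: donor residue (N1 + H1), acceptor residue (O2)
hb_structure <- function() {
  ribonet:::new_structure(data.frame(
    type = "ATOM", eleno = 1:3, elety = c("N1", "H1", "O2"),
    resid = c("G", "G", "U"), chain = "A", resno = c(1, 1, 2), insert = "",
    x = c(0, 1, 3), y = 0, z = 0,
    elesy = c("N", "H", "O"), stringsAsFactors = FALSE))
}

test_that("hydrogen-bond hits require both distance and near-linearity", {
  crit <- hbond_criterion()
  donors <- data.frame(d = 1L, h = 2L)
  run1 <- function(A) {
    coords <- rbind(c(0, 0, 0), c(1, 0, 0), A)
    nrow(detect_hbonds_frame(coords, donors, acceptors = 3L, crit))
  }
  A <- place_acceptor(175, 2.0)           # D-A ~3.0 A, angle 175 deg
  expect_lt(sqrt(sum(A^2)), 3.5)
  expect_equal(run1(A), 1)

  A <- place_acceptor(180, 2.6)           # collinear but D-A = 3.6 A
  expect_equal(sqrt(sum(A^2)), 3.6, tolerance = 1e-12)
  expect_equal(run1(A), 0)

  A <- place_acceptor(140, 1.6)           # D-A ~2.45 A but 40 deg deviation
  expect_lt(sqrt(sum(A^2)), 3.5)
  expect_equal(run1(A), 0)

  # boundary: exactly 30 deg deviation is accepted (<= cutoff)
  A <- place_acceptor(150, 1.9)
  expect_equal(run1(A), 1)
})

test_that("occupancy counts criterion frames exactly", {
  s <- hb_structure()
  good <- rbind(c(0, 0, 0), c(1, 0, 0), c(2.9, 0, 0))   # linear, 2.9 A
  bad  <- rbind(c(0, 0, 0), c(1, 0, 0), c(5.0, 0, 0))
  frames <- c(replicate(68, good, simplify = FALSE),
              replicate(32, bad, simplify = FALSE))
  trj <- traj_from_frames(s, frames)
  pairs <- data.frame(donor_resno = 1, donor_name = "N1",
                      acceptor_resno = 2, acceptor_name = "O2")
  occ <- hbond_occupancy(trj, pairs)
  expect_equal(occ$frames_observed, 68)
  expect_equal(occ$occupancy, 68)

  none <- traj_from_frames(s, replicate(40, bad, simplify = FALSE))
  expect_equal(hbond_occupancy(none, pairs)$occupancy, 0)

  # a donor with no attached hydrogen is a definition error
  pairs_bad <- data.frame(donor_resno = 2, donor_name = "O2",
                          acceptor_resno = 1, acceptor_name = "N1")
  expect_error(hbond_occupancy(trj, pairs_bad), "no attached hydrogen")
  pairs_missing <- data.frame(donor_resno = 1, donor_name = "N9",
                              acceptor_resno = 2, acceptor_name = "O2")
  expect_error(hbond_occupancy(trj, pairs_missing), "cannot resolve")
})

test_that("planted Bernoulli occupancy is recovered within the binomial bound", {
  spec <- synthetic_spec(n_residues = 20, n_frames = 2000,
                         hbonds = list(list(donor = 4, acceptor = 17,
                                            occupancy = 0.9)),
                         seed = 123)
  trj <- make_trajectory(make_reference(spec), spec)
  occ <- hbond_occupancy(trj, default_pairs(spec))
  expect_lt(abs(occ$occupancy - 90), 2)   # ~3 binomial SEs
})

test_that("occupancy under concatenation is the frame-weighted average", {
  s <- hb_structure()
  good <- rbind(c(0, 0, 0), c(1, 0, 0), c(2.9, 0, 0))
  bad  <- rbind(c(0, 0, 0), c(1, 0, 0), c(5.0, 0, 0))
  a <- traj_from_frames(s, c(replicate(30, good, simplify = FALSE),
                             replicate(10, bad, simplify = FALSE)))   # 75%
  b <- traj_from_frames(s, c(replicate(6, good, simplify = FALSE),
                             replicate(54, bad, simplify = FALSE)))   # 10%
  pairs <- data.frame(donor_resno = 1, donor_name = "N1",
                      acceptor_resno = 2, acceptor_name = "O2")
  oa <- hbond_occupancy(a, pairs)$occupancy
  ob <- hbond_occupancy(b, pairs)$occupancy
  oc <- hbond_occupancy(concat_trajectories(a, b), pairs)$occupancy
  expect_equal(oc, (40 * oa + 60 * ob) / 100, tolerance = 1e-12)
})

test_that("pair distance statistics reproduce closed forms", {
  s <- hb_structure()
  static <- rbind(c(0, 0, 0), c(1, 0, 0), c(1.85, 0, 0))
  trj <- traj_from_frames(s, replicate(20, static, simplify = FALSE))
  pairs <- data.frame(a_resno = 1, a_name = "N1", b_resno = 2, b_name = "O2")
  st <- distance_stats(trj, pairs)
  expect_equal(st$mean_dist, 1.85, tolerance = 1e-12)
  expect_equal(st$sd_dist, 0, tolerance = 1e-12)

  two <- rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0))
  four <- rbind(c(0, 0, 0), c(1, 0, 0), c(4, 0, 0))
  alt <- traj_from_frames(s, rep(list(two, four), 10))
  st <- distance_stats(alt, pairs)
  expect_equal(st$mean_dist, 3)
  expect_equal(st$sd_dist, sd(rep(c(2, 4), 10)), tolerance = 1e-12)

  # planted Gaussian jitter on the distance: SD recovered within 5%
  set.seed(9)
  d <- 3 + rnorm(5000, sd = 0.2)
  frames <- lapply(d, function(dd) rbind(c(0, 0, 0), c(1, 0, 0), c(dd, 0, 0)))
  st <- distance_stats(traj_from_frames(s, frames), pairs)
  expect_lt(abs(st$sd_dist / 0.2 - 1), 0.05)
})

test_that("contact mask applies a strict distance cutoff and >= persistence", {
  pos <- rbind(c(0, 0, 0), c(10, 0, 0))
  s <- point_structure(pos)
  near <- rbind(c(0, 0, 0), c(3, 0, 0))
  far <- rbind(c(0, 0, 0), c(6, 0, 0))

  m <- contact_mask(traj_from_frames(s, replicate(10, near, simplify = FALSE)))
  expect_true(m$mask[1, 2])
  expect_true(all(diag(m$mask)))

  m74 <- contact_mask(traj_from_frames(
    s, c(replicate(74, near, simplify = FALSE),
         replicate(26, far, simplify = FALSE))))
  expect_false(m74$mask[1, 2])
  expect_equal(m74$fraction[1, 2], 0.74)

  m75 <- contact_mask(traj_from_frames(
    s, c(replicate(75, near, simplify = FALSE),
         replicate(25, far, simplify = FALSE))))
  expect_true(m75$mask[1, 2])
})

test_that("contact mask equals a naive double-loop recomputation", {
  spec <- synthetic_spec(n_residues = 8, n_frames = 30, sigma = 1.2, seed = 55)
  ref <- make_reference(spec)
  trj <- make_trajectory(ref, spec)
  m <- contact_mask(trj)

  heavy <- select_atoms(ref, "heavy")
  res_of <- ref$atom$res_index[heavy$atom]
  counts <- matrix(0, 8, 8)
  for (f in seq_len(n_frames(trj))) {
    co <- ribonet:::frame_coords(trj, f)[heavy$atom, ]
    for (i in 1:7) for (j in (i + 1):8) {
      di <- co[res_of == i, , drop = FALSE]
      dj <- co[res_of == j, , drop = FALSE]
      dmin <- min(sqrt(outer(rowSums(di^2), rowSums(dj^2), "+") -
                       2 * tcrossprod(di, dj)))
      if (dmin < 4.5) counts[i, j] <- counts[j, i] <- counts[i, j] + 1
    }
  }
  naive <- counts / n_frames(trj) >= 0.75
  diag(naive) <- TRUE
  expect_identical(unname(m$mask), naive)
})

test_that("contact mask is invariant to rigid-body motion of whole frames", {
  spec <- synthetic_spec(n_residues = 10, n_frames = 25, seed = 66)
  trj <- make_trajectory(make_reference(spec), spec)
  m1 <- contact_mask(trj)
  m2 <- contact_mask(perturb_rigid(trj, seed = 7))
  expect_identical(m1$mask, m2$mask)
  expect_equal(m1$fraction, m2$fraction, tolerance = 1e-12)
})
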