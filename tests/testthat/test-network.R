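test_that("edge weights follow -log|C| with the contact filter applied", {
  C <- diag(4)
  C[1, 2] <- C[2, 1] <- 1          # perfect coupling
  C[2, 3] <- C[3, 2] <- exp(-1)    # weight exactly 1
  C[3, 4] <- C[4, 3] <- 0.5
  C[1, 3] <- C[3, 1] <- 0          # uncoupled: no edge
  C[1, 4] <- C[4, 1] <- 0.9        # masked away below
  labels <- as.character(1:4)
  dimnames(C) <- list(labels, labels)
  dccm <- structure(C, class = c("dccm_mat", "matrix"))
  mask <- matrix(TRUE, 4, 4, dimnames = list(labels, labels))
  mask[1, 4] <- mask[4, 1] <- FALSE
  cm <- structure(list(mask = mask, fraction = mask * 1, cutoff = 4.5,
                       persistence = 0.75, selection = "heavy"),
                  class = "contact_mask")
  net <- build_network(dccm, cm)

  expect_equal(net$weights[1, 2], 0)
  expect_equal(net$weights[2, 3], 1, tolerance = 1e-12)
  expect_equal(net$weights[3, 4], 0.6931472, tolerance = 1e-7)
  expect_equal(net$weights[3, 4], -log(0.5), tolerance = 1e-15)
  expect_identical(net$adjacency[1, 3], 0L)     # |C| = 0: no edge
  expect_false(is.finite(net$weights[1, 3]))
  expect_identical(net$adjacency[1, 4], 0L)     # contact filter wins
  expect_true(all(diag(net$adjacency) == 0))    # no self-loops
  expect_identical(net$adjacency, t(net$adjacency))

  # base-2 logarithm option
  net2 <- build_network(dccm, cm, log_base = 2)
  expect_equal(net2$weights[3, 4], 1, tolerance = 1e-12)

  # increasing |C| on an edge never increases its weight
  set.seed(5)
  for (r in 1:50) {
    c1 <- runif(1, 0.05, 0.95); c2 <- runif(1, c1, 0.999)
    expect_lte(-log(c2), -log(c1))
  }
})

test_that("display-threshold filtering does not alter the network itself", {
  W <- random_weight_matrix(6, p = 0.8)
  net <- network_from_weights(W)
  el_all <- edge_list(net)
  el_vis <- edge_list(net, threshold = 0.6)
  expect_true(nrow(el_vis) <= nrow(el_all))
  expect_true(all(abs(el_vis$cij) > 0.6))
  expect_equal(sum(net$adjacency) / 2, nrow(el_all))
})

test_that("betweenness matches hand-computed small graphs", {
  # path graph a-b-c: all traffic crosses b
  Wp <- matrix(Inf, 3, 3); diag(Wp) <- 0
  Wp[1, 2] <- Wp[2, 1] <- 1; Wp[2, 3] <- Wp[3, 2] <- 1
  b <- betweenness_profile(network_from_weights(Wp))
  expect_equal(unname(b), c(0, 1, 0))

  # 4-cycle: two geodesics between opposite corners, each node on one
  Wc <- matrix(Inf, 4, 4); diag(Wc) <- 0
  for (e in list(c(1, 2), c(2, 3), c(3, 4), c(4, 1)))
    Wc[e[1], e[2]] <- Wc[e[2], e[1]] <- 1
  b <- betweenness_profile(network_from_weights(Wc))
  expect_equal(unname(b), rep(0.5, 4))

  # ordered doubles; normalisation divides by (n-1)(n-2)/2
  expect_equal(unname(betweenness_profile(network_from_weights(Wp),
                                          ordered = TRUE)), c(0, 2, 0))
  expect_equal(unname(betweenness_profile(network_from_weights(Wp),
                                          normalized = TRUE)), c(0, 1, 0))
})

test_that("betweenness equals exhaustive enumeration on random graphs", {
  set.seed(7)
  for (r in 1:60) {
    n <- sample(4:8, 1)
    W <- random_weight_matrix(n, p = 0.4)
    net <- network_from_weights(W)
    got <- unname(betweenness_profile(net))
    expect_equal(got, brute_betweenness(net$weights), tolerance = 1e-9)
  }
})

test_that("betweenness and eigenvector centrality agree with igraph", {
  skip_if_not_installed("igraph")
  set.seed(8)
  W <- random_weight_matrix(30, p = 0.15)
  net <- network_from_weights(W)
  A <- net$weights; A[!is.finite(A)] <- 0; diag(A) <- 0
  g <- igraph::graph_from_adjacency_matrix(A, mode = "undirected",
                                           weighted = TRUE)
  expect_equal(unname(betweenness_profile(net)),
               unname(igraph::betweenness(g, weights = igraph::E(g)$weight)),
               tolerance = 1e-9)

  gs <- igraph::graph_from_adjacency_matrix(net$strength, mode = "undirected",
                                            weighted = TRUE)
  ig_ev <- igraph::eigen_centrality(gs, weights = igraph::E(gs)$weight)$vector
  expect_equal(as.numeric(eigenvector_profile(net)), unname(ig_ev),
               tolerance = 1e-6)
})

test_that("eigenvector centrality follows Perron-Frobenius expectations", {
  # two nodes, one edge: symmetric, both maximal
  W2 <- matrix(c(0, 0.7, 0.7, 0), 2, 2)
  W2[W2 == 0] <- Inf; diag(W2) <- 0
  ev <- eigenvector_profile(network_from_weights(W2))
  expect_equal(as.numeric(ev), c(1, 1), tolerance = 1e-12)

  # star K1,3 with equal weights: centre strictly above the leaves
  Ws <- matrix(Inf, 4, 4); diag(Ws) <- 0
  Ws[1, 2:4] <- Ws[2:4, 1] <- 0.9
  ev <- eigenvector_profile(network_from_weights(Ws))
  expect_equal(as.numeric(ev[1]), 1)
  expect_true(all(ev[2:4] < 1))
  expect_true(all(ev >= 0))

  # random 8-node graph vs power iteration
  set.seed(9)
  for (r in 1:20) {
    W <- random_weight_matrix(8, p = 0.5)
    net <- network_from_weights(W)
    ev <- eigenvector_profile(net)
    expect_equal(as.numeric(ev), as.numeric(power_iteration(net$strength)),
                 tolerance = 1e-8)
  }
})

test_that("eigenvector centrality is computed on the largest component only", {
  W <- matrix(Inf, 5, 5); diag(W) <- 0
  W[1, 2] <- W[2, 1] <- 0.5; W[2, 3] <- W[3, 2] <- 0.5
  W[4, 5] <- W[5, 4] <- 0.2      # separate 2-node component
  ev <- eigenvector_profile(network_from_weights(W))
  expect_true(all(ev[1:3] > 0))
  expect_equal(as.numeric(ev[4:5]), c(0, 0))

  empty <- matrix(Inf, 3, 3); diag(empty) <- 0
  expect_error(eigenvector_profile(network_from_weights(empty)), "no edges")
})

test_that("SIP reproduces its analytic values and scale invariance", {
  expect_equal(sip(c(1, 2, 3), c(1, 2, 3)), 1, tolerance = 1e-12)
  expect_equal(sip(c(1, 0), c(0, 1)), 0)
  expect_equal(sip(c(1, 2), c(2, 1)), 16 / 25)  # = 0.64

  set.seed(10)
  for (r in 1:25) {
    a <- runif(12); b <- runif(12)
    expect_equal(sip(a, b), sip(7.3 * a, b), tolerance = 1e-12)
    expect_equal(sip(a, b), sip(a, 0.002 * b), tolerance = 1e-12)
    expect_gte(sip(a, b), 0); expect_lte(sip(a, b), 1 + 1e-12)
    expect_equal(sip(a, b), sip(b, a), tolerance = 1e-12)
  }
  expect_error(sip(c(0, 0), c(1, 1)), "all-zero")
  expect_error(sip(1:3, 1:4), "differ in length")
})

test_that("planted correlated blocks gain eigenvector centrality", {
  spec <- synthetic_spec(n_residues = 40, n_frames = 2500,
    correlation_blocks = list(list(residues = 12:16, rho = 0.8)), seed = 23)
  trj <- make_trajectory(make_reference(spec), spec)
  sel <- select_atoms(trj$topology, "C5'")
  C <- compute_dccm(trj, sel)
  mask <- contact_mask(trj)
  net <- build_network(C, mask)
  ev <- eigenvector_profile(net)
  block <- 12:16
  expect_gt(mean(ev[block]), mean(ev[-block]))
})
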