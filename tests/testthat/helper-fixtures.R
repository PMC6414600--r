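# Fixtures and independent oracles shared across the suite.
# All fixtures are built in code; nothing is read from disk.

# structure with one named atom per residue at given positions (n x 3)
point_structure <- function(positions, atom_name = "C5'", elesy = "C") {
  n <- nrow(positions)
  ribonet:::new_structure(data.frame(
    type = "ATOM", eleno = seq_len(n), elety = atom_name,
    resid = "G", chain = "A", resno = seq_len(n), insert = "",
    x = positions[, 1], y = positions[, 2], z = positions[, 3],
    elesy = elesy, stringsAsFactors = FALSE))
}

# trajectory from a list of n x 3 coordinate matrices
traj_from_frames <- function(topology, frames) {
  xyz <- do.call(rbind, lapply(frames, function(m) as.numeric(t(m))))
  trajectory_from_xyz(topology, xyz)
}

# wrap an explicit weight matrix (Inf = no edge) as a residue network:
# goes through build_network so construction rules are exercised too
network_from_weights <- function(W) {
  n <- nrow(W)
  C <- exp(-W)
  C[!is.finite(W)] <- 0
  diag(C) <- 1
  labels <- as.character(seq_len(n))
  dimnames(C) <- list(labels, labels)
  dccm <- structure(C, class = c("dccm_mat", "matrix"))
  mask <- structure(list(mask = matrix(TRUE, n, n, dimnames = list(labels, labels)),
                         fraction = matrix(1, n, n),
                         cutoff = 4.5, persistence = 0.75, selection = "heavy"),
                    class = "contact_mask")
  build_network(dccm, mask)
}

# random connected-ish weighted graph on n nodes (weight matrix)
random_weight_matrix <- function(n, p = 0.5, wmin = 0.1, wmax = 2) {
  W <- matrix(Inf, n, n)
  for (i in seq_len(n - 1)) {
    # spanning chain keeps most graphs connected
    W[i, i + 1] <- W[i + 1, i] <- round(stats::runif(1, wmin, wmax), 3)
  }
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (j > i + 1 && stats::runif(1) < p)
      W[i, j] <- W[j, i] <- round(stats::runif(1, wmin, wmax), 3)
  }
  diag(W) <- 0
  W
}

# ---- oracles ---------------------------------------------------------------

# all simple paths s -> t sorted by (length, lexicographic node sequence),
# grouping float-tied lengths with a tolerance
enumerate_simple_paths <- function(W, s, t, eps = 1e-9) {
  n <- nrow(W)
  res <- list()
  recurse <- function(path, len) {
    u <- path[length(path)]
    if (u == t) {
      res[[length(res) + 1]] <<- list(path = path, len = len)
      return()
    }
    for (v in seq_len(n)) {
      if (v != u && is.finite(W[u, v]) && !(v %in% path))
        recurse(c(path, v), len + W[u, v])
    }
  }
  recurse(s, 0)
  if (length(res) == 0) return(res)
  lens <- vapply(res, `[[`, numeric(1), "len")
  grp <- cumsum(c(TRUE, diff(sort(lens)) > eps))
  rank_of <- grp[match(lens, sort(lens))]
  keys <- vapply(res, function(r) paste(sprintf("%04d", r$path), collapse = ""),
                 character(1))
  res[order(rank_of, keys)]
}

# exhaustive betweenness: enumerate geodesics for every unordered pair
brute_betweenness <- function(W, eps = 1e-9) {
  n <- nrow(W)
  cb <- numeric(n)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    all_p <- enumerate_simple_paths(W, i, j, eps)
    if (length(all_p) == 0) next
    lens <- vapply(all_p, `[[`, numeric(1), "len")
    geo <- all_p[lens <= min(lens) + eps]
    sigma <- length(geo)
    for (v in seq_len(n)) {
      if (v == i || v == j) next
      sv <- sum(vapply(geo, function(g) v %in% g$path, logical(1)))
      cb[v] <- cb[v] + sv / sigma
    }
  }
  cb
}

# power-iteration leading eigenvector of a non-negative symmetric matrix,
# normalised to unit maximum. A positive diagonal shift keeps the Perron
# vector unchanged while breaking the +/-lambda symmetry of bipartite graphs
# (e.g. path graphs), where unshifted power iteration never converges.
power_iteration <- function(S, iter = 10000, tol = 1e-14) {
  Sh <- S + diag(1, nrow(S))
  v <- rep(1, nrow(S))
  for (k in seq_len(iter)) {
    w <- Sh %*% v
    w <- as.numeric(w) / sqrt(sum(w^2))
    if (max(abs(w - v)) < tol) break
    v <- w
  }
  v / max(v)
}

# tiny two-system synthetic config for pipeline tests
demo_config <- function(seed = 42, n_frames = 120) {
  mkspec <- function(s, rho) synthetic_spec(
    n_residues = 20, n_frames = n_frames,
    correlation_blocks = list(list(residues = 5:8, rho = rho)),
    hbonds = list(list(donor = 4, acceptor = 17, occupancy = 0.7)),
    seed = s)
  run_config(
    systems = list(apo = list(synthetic = mkspec(seed, 0.5)),
                   holo = list(synthetic = mkspec(seed + 1, 0.8))),
    params = list(source = "4", sink = "17", k_paths = 25),
    comparisons = list(c("apo", "holo")),
    seed = seed)
}
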