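# Contact-filtered correlation networks, centrality profiles, and SIP.
#
# Two matrices live on the same edge set: shortest-path machinery uses the
# distance weights w_ij = -log|C_ij| ("smaller = closer"), while eigenvector
# centrality uses the coupling strengths |C_ij| ("bigger = stronger").

#' Build a residue interaction network from a DCCM and a contact mask
#'
#' An undirected edge joins residues i != j when the contact mask is TRUE and
#' `|C_ij| > 0`. Edge weights are `w_ij = -log(|C_ij|)` (natural log by
#' default): perfectly coupled pairs (`|C| = 1`) are at distance 0, uncoupled
#' pairs have no edge.
#'
#' @param dccm a `dccm_mat`.
#' @param mask a `contact_mask` over the same residues (labels must match).
#' @param log_base logarithm base for the edge weights (default `exp(1)`).
#' @return a `residue_network`: labels, adjacency (0/1), `weights`
#'   (-log|C| distances, Inf where no edge), `strength` (|C| on edges, 0
#'   elsewhere), `cij` (signed correlations), and filter provenance.
#' @export
build_network <- function(dccm, mask, log_base = exp(1)) {
  C <- unclass(dccm)
  M <- mask$mask
  if (!identical(dimnames(C)[[1]], dimnames(M)[[1]]))
    stopf("DCCM and contact mask cover different residues")
  n <- nrow(C)
  absC <- abs(C)
  edge <- M & absC > 0
  diag(edge) <- FALSE
  W <- matrix(Inf, n, n)
  W[edge] <- -log(absC[edge]) / log(log_base)
  diag(W) <- 0
  S <- matrix(0, n, n)
  S[edge] <- absC[edge]
  A <- matrix(0L, n, n)
  A[edge] <- 1L
  dimnames(A) <- dimnames(W) <- dimnames(S) <- dimnames(C)
  structure(
    list(labels = rownames(C), n = n, adjacency = A, weights = W,
         strength = S, cij = C,
         filter = list(cutoff = mask$cutoff, persistence = mask$persistence,
                       log_base = log_base)),
    class = "residue_network"
  )
}

#' @export
print.residue_network <- function(x, ...) {
  cat(sprintf("<residue network> %d nodes, %d edges (contact filter %.1f A / %.0f%%)\n",
              x$n, sum(x$adjacency) / 2, x$filter$cutoff, 100 * x$filter$persistence))
  invisible(x)
}

#' Filter network edges for display
#'
#' Returns the edge list restricted to `|C_ij| > threshold` — a rendering
#' convenience that never affects network construction or path analysis.
#'
#' @param network a `residue_network`.
#' @param threshold minimum `|C|` (default 0.6).
#' @return data.frame with columns from, to, cij, weight.
#' @export
edge_list <- function(network, threshold = 0) {
  idx <- which(upper.tri(network$adjacency) & network$adjacency == 1 &
               abs(network$cij) > threshold, arr.ind = TRUE)
  data.frame(from = network$labels[idx[, 1]],
             to = network$labels[idx[, 2]],
             cij = network$cij[idx],
             weight = network$weights[idx])
}

# --- shortest-path internals -------------------------------------------------

# Dijkstra over a weight matrix (Inf = no edge). Returns distances, geodesic
# counts sigma, and predecessor lists (all shortest-path DAG edges).
# eps handles floating-point ties in path lengths.
dijkstra_full <- function(W, source, eps = 1e-10) {
  n <- nrow(W)
  dist <- rep(Inf, n); dist[source] <- 0
  sigma <- rep(0, n); sigma[source] <- 1
  preds <- vector("list", n)
  done <- rep(FALSE, n)
  repeat {
    u <- which(!done & is.finite(dist))
    if (length(u) == 0) break
    u <- u[which.min(dist[u])]
    done[u] <- TRUE
    nb <- which(is.finite(W[u, ]) & !done & seq_len(n) != u)
    for (v in nb) {
      alt <- dist[u] + W[u, v]
      if (!is.finite(dist[v])) {
        dist[v] <- alt
        sigma[v] <- sigma[u]
        preds[[v]] <- u
        next
      }
      tol <- eps * max(1, abs(dist[v]))
      if (alt < dist[v] - tol) {
        dist[v] <- alt
        sigma[v] <- sigma[u]
        preds[[v]] <- u
      } else if (abs(alt - dist[v]) <= tol) {
        sigma[v] <- sigma[v] + sigma[u]
        preds[[v]] <- c(preds[[v]], u)
      }
    }
  }
  list(dist = dist, sigma = sigma, preds = preds)
}

# Dijkstra returning one explicit shortest path source -> sink, breaking
# length ties toward the lexicographically smallest node-index sequence.
dijkstra_path <- function(W, source, sink, eps = 1e-10) {
  n <- nrow(W)
  dist <- rep(Inf, n); dist[source] <- 0
  paths <- vector("list", n); paths[[source]] <- source
  done <- rep(FALSE, n)
  repeat {
    u <- which(!done & is.finite(dist))
    if (length(u) == 0) break
    u <- u[which.min(dist[u])]
    done[u] <- TRUE
    if (u == sink) break
    nb <- which(is.finite(W[u, ]) & !done & seq_len(n) != u)
    for (v in nb) {
      alt <- dist[u] + W[u, v]
      cand <- c(paths[[u]], v)
      if (!is.finite(dist[v])) {
        dist[v] <- alt; paths[[v]] <- cand
        next
      }
      tol <- eps * max(1, abs(dist[v]))
      if (alt < dist[v] - tol) {
        dist[v] <- alt; paths[[v]] <- cand
      } else if (abs(alt - dist[v]) <= tol && lex_less(cand, paths[[v]])) {
        paths[[v]] <- cand
      }
    }
  }
  if (!is.finite(dist[sink])) return(NULL)
  list(path = paths[[sink]], length = dist[sink])
}

# lexicographic comparison of integer sequences (shorter prefix wins)
lex_less <- function(a, b) {
  if (is.null(b)) return(TRUE)
  k <- min(length(a), length(b))
  for (i in seq_len(k)) {
    if (a[i] < b[i]) return(TRUE)
    if (a[i] > b[i]) return(FALSE)
  }
  length(a) < length(b)
}

#' Betweenness centrality profile
#'
#' Weighted shortest-path betweenness (Brandes' algorithm): for each node n,
#' the sum over pairs (i, j), i != j != n, of the fraction of geodesics
#' between i and j passing through n, with path length defined as the sum of
#' the `-log|C|` edge weights. By default pairs are unordered and the value is
#' unnormalised (raw pair counts). Disconnected pairs contribute zero.
#'
#' @param network a `residue_network`.
#' @param ordered if TRUE, count ordered pairs (doubles every value).
#' @param normalized if TRUE, divide by the number of pairs not involving the
#'   node, `(n-1)(n-2)/2` (unordered), for cross-size comparison.
#' @return named numeric vector of betweenness values per node.
#' @export
betweenness_profile <- function(network, ordered = FALSE, normalized = FALSE) {
  W <- network$weights
  n <- network$n
  if (n == 0) stopf("empty network")
  cb <- numeric(n)
  for (s in seq_len(n)) {
    dj <- dijkstra_full(W, s)
    order_idx <- order(dj$dist)
    order_idx <- order_idx[is.finite(dj$dist[order_idx])]
    delta <- numeric(n)
    for (w in rev(order_idx)) {
      for (v in dj$preds[[w]]) {
        delta[v] <- delta[v] + dj$sigma[v] / dj$sigma[w] * (1 + delta[w])
      }
      if (w != s) cb[w] <- cb[w] + delta[w]
    }
  }
  if (!ordered) cb <- cb / 2
  if (normalized) {
    denom <- (n - 1) * (n - 2) / (if (ordered) 1 else 2)
    cb <- if (denom > 0) cb / denom else cb * 0
  }
  stats::setNames(cb, network$labels)
}

# connected components of the adjacency matrix (BFS)
graph_components <- function(A) {
  n <- nrow(A)
  comp <- rep(NA_integer_, n)
  cid <- 0L
  for (s in seq_len(n)) {
    if (!is.na(comp[s])) next
    cid <- cid + 1L
    queue <- s; comp[s] <- cid
    while (length(queue) > 0) {
      u <- queue[1]; queue <- queue[-1]
      nb <- which(A[u, ] > 0 & is.na(comp))
      comp[nb] <- cid
      queue <- c(queue, nb)
    }
  }
  comp
}

#' Eigenvector centrality profile
#'
#' Leading eigenvector of the coupling-strength matrix (`|C_ij|` on edges):
#' a node is central when connected to other central nodes, with stronger
#' couplings contributing more. Computed on the largest connected component
#' (non-negative by Perron-Frobenius), normalised to unit maximum; nodes
#' outside that component get 0. The reciprocal of the leading eigenvalue is
#' returned as attribute `alpha`.
#'
#' @param network a `residue_network`.
#' @return named numeric vector in [0, 1] with attribute `alpha`.
#' @export
eigenvector_profile <- function(network) {
  if (network$n == 0 || sum(network$adjacency) == 0)
    stopf("empty network: no edges")
  comp <- graph_components(network$adjacency)
  main <- which.max(tabulate(comp))
  idx <- which(comp == main)
  S <- network$strength[idx, idx, drop = FALSE]
  e <- eigen(S, symmetric = TRUE)
  v <- e$vectors[, 1]
  if (sum(v) < 0) v <- -v
  v[v < 0] <- 0            # clip tiny negative round-off
  out <- numeric(network$n)
  out[idx] <- v / max(v)
  out <- stats::setNames(out, network$labels)
  attr(out, "alpha") <- 1 / e$values[1]
  out
}

#' Both centrality profiles as a table
#'
#' @param network a `residue_network`.
#' @inheritParams betweenness_profile
#' @return data.frame with node, betweenness, eigenvector.
#' @export
centrality_table <- function(network, ordered = FALSE, normalized = FALSE) {
  b <- betweenness_profile(network, ordered = ordered, normalized = normalized)
  ev <- eigenvector_profile(network)
  data.frame(node = network$labels, betweenness = as.numeric(b),
             eigenvector = as.numeric(ev))
}

#' Square inner product (SIP) between two per-node profiles
#'
#' `SIP = (w_A' w_B)^2 / ((w_A' w_A)(w_B' w_B))` — the squared cosine of the
#' angle between the two profiles: 1 for proportional profiles, 0 for
#' orthogonal ones. Invariant to positive rescaling of either profile.
#'
#' @param profile_a,profile_b numeric vectors of equal length, not all zero.
#' @return similarity in [0, 1].
#' @export
sip <- function(profile_a, profile_b) {
  a <- as.numeric(profile_a); b <- as.numeric(profile_b)
  if (length(a) != length(b)) stopf("profiles differ in length")
  na2 <- sum(a^2); nb2 <- sum(b^2)
  if (na2 == 0 || nb2 == 0) stopf("SIP undefined for an all-zero profile")
  (sum(a * b))^2 / (na2 * nb2)
}
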