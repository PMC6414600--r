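# Yen k-shortest-path ensembles between designated residues, node degeneracy,
# and nodes-per-path summaries.

resolve_node <- function(network, node) {
  if (is.character(node)) {
    i <- match(node, network$labels)
    if (is.na(i)) stopf("node '%s' not in network", node)
    i
  } else {
    i <- as.integer(node)
    if (i < 1 || i > network$n) stopf("node index %d out of range", i)
    i
  }
}

path_length <- function(W, path) {
  if (length(path) < 2) return(0)
  sum(W[cbind(path[-length(path)], path[-1])])
}

#' Yen's k shortest loopless paths
#'
#' Collects up to `k` simple paths from `source` to `sink` in non-decreasing
#' order of length (sum of `-log|C|` edge weights). Ties in length are broken
#' toward the lexicographically smallest node-index sequence, making the
#' ensemble deterministic. When fewer than `k` simple paths exist the
#' ensemble saturates without error; a disconnected source/sink pair yields
#' an empty ensemble with `k_found = 0`.
#'
#' @param network a `residue_network`.
#' @param source,sink node labels (residue numbers as character) or indices;
#'   must differ.
#' @param k maximum number of paths (default 1000, the conventional ensemble
#'   size for communication analysis).
#' @return a `path_ensemble`: source, sink, list of paths (integer node
#'   sequences), lengths, `k_requested`, `k_found`, node labels.
#' @export
yen_k_shortest <- function(network, source, sink, k = 1000) {
  if (k < 1) stopf("k must be >= 1")
  s <- resolve_node(network, source)
  t <- resolve_node(network, sink)
  if (s == t) stopf("source and sink must differ")
  W <- network$weights
  diag(W) <- Inf

  first <- dijkstra_path(W, s, t)
  if (is.null(first)) {
    return(structure(
      list(source = network$labels[s], sink = network$labels[t],
           paths = list(), lengths = numeric(0),
           k_requested = k, k_found = 0L, labels = network$labels,
           disconnected = TRUE),
      class = "path_ensemble"))
  }

  A <- list(first$path)
  Alen <- first$length
  B_paths <- list(); B_len <- numeric(0); B_keys <- character(0)
  path_key <- function(p) paste(p, collapse = "-")
  A_keys <- path_key(first$path)

  while (length(A) < k) {
    prev <- A[[length(A)]]
    for (j in seq_len(length(prev) - 1)) {
      spur_node <- prev[j]
      root <- prev[seq_len(j)]
      W2 <- W
      # remove edges taken by accepted paths sharing this root
      for (p in A) {
        if (length(p) > j && identical(p[seq_len(j)], root)) {
          W2[p[j], p[j + 1]] <- Inf
          W2[p[j + 1], p[j]] <- Inf
        }
      }
      # remove root nodes other than the spur node
      if (j > 1) {
        gone <- root[seq_len(j - 1)]
        W2[gone, ] <- Inf
        W2[, gone] <- Inf
      }
      spur <- dijkstra_path(W2, spur_node, t)
      if (is.null(spur)) next
      total <- c(root[-j], spur$path)
      key <- path_key(total)
      if (key %in% A_keys || key %in% B_keys) next
      B_paths[[length(B_paths) + 1]] <- total
      B_len <- c(B_len, path_length(W, total))
      B_keys <- c(B_keys, key)
    }
    if (length(B_paths) == 0) break
    # pick the candidate with smallest (length, lexicographic sequence)
    best <- which(B_len <= min(B_len) + 1e-12)
    if (length(best) > 1) {
      bi <- best[1]
      for (cand in best[-1])
        if (lex_less(B_paths[[cand]], B_paths[[bi]])) bi <- cand
      best <- bi
    }
    A[[length(A) + 1]] <- B_paths[[best]]
    Alen <- c(Alen, B_len[best])
    A_keys <- c(A_keys, B_keys[best])
    B_paths <- B_paths[-best]; B_len <- B_len[-best]; B_keys <- B_keys[-best]
  }

  structure(
    list(source = network$labels[s], sink = network$labels[t],
         paths = A, lengths = Alen,
         k_requested = k, k_found = length(A), labels = network$labels,
         disconnected = FALSE),
    class = "path_ensemble"
  )
}

#' @export
print.path_ensemble <- function(x, ...) {
  if (x$k_found == 0) {
    cat(sprintf("<path ensemble> %s -> %s: disconnected (0 paths)\n",
                x$source, x$sink))
  } else {
    cat(sprintf("<path ensemble> %s -> %s: %d/%d paths, lengths %.3f .. %.3f\n",
                x$source, x$sink, x$k_found, x$k_requested,
                min(x$lengths), max(x$lengths)))
  }
  invisible(x)
}

#' Node degeneracy of a path ensemble
#'
#' For every network node, the fraction of ensemble paths that contain it
#' (paths found, not paths requested). Source and sink have degeneracy 1 by
#' construction.
#'
#' @param ensemble a `path_ensemble` with at least one path.
#' @return named numeric vector in [0, 1] over all network nodes.
#' @export
node_degeneracy <- function(ensemble) {
  if (ensemble$k_found == 0) stopf("empty ensemble: no paths found")
  n <- length(ensemble$labels)
  counts <- integer(n)
  for (p in ensemble$paths) counts[p] <- counts[p] + 1L
  stats::setNames(counts / ensemble$k_found, ensemble$labels)
}

#' Nodes-per-path distribution
#'
#' @param ensemble a `path_ensemble` with at least one path.
#' @return list with `counts` (per-path node counts), `mean`, `median`.
#' @export
nodes_per_path <- function(ensemble) {
  if (ensemble$k_found == 0) stopf("empty ensemble: no paths found")
  counts <- vapply(ensemble$paths, length, integer(1))
  list(counts = counts, mean = mean(counts), median = stats::median(counts))
}

#' Centrality of path nodes vs the whole network
#'
#' Summarises a centrality profile over (a) all network nodes and (b) the
#' nodes participating in the ensemble — each node counted once by default,
#' or weighted by the number of paths it appears on (`mode = "multiset"`).
#'
#' @param ensemble a `path_ensemble`.
#' @param betweenness,eigenvector named centrality vectors covering all
#'   ensemble nodes (from [betweenness_profile()] / [eigenvector_profile()]).
#' @param mode `"unique"` (default) or `"multiset"`.
#' @return data.frame with one row per (centrality, group) combination and
#'   columns min, q1, median, q3, max, mean, n.
#' @export
path_centrality_summary <- function(ensemble, betweenness, eigenvector,
                                    mode = c("unique", "multiset")) {
  mode <- match.arg(mode)
  if (ensemble$k_found == 0) stopf("empty ensemble: no paths found")
  for (prof in list(betweenness, eigenvector)) {
    if (length(prof) != length(ensemble$labels))
      stopf("centrality profile does not cover all network nodes")
  }
  path_nodes <- if (mode == "unique") sort(unique(unlist(ensemble$paths)))
                else sort(unlist(ensemble$paths))
  summarise <- function(v, label, group) {
    q <- stats::quantile(v, c(0, 0.25, 0.5, 0.75, 1), names = FALSE)
    data.frame(centrality = label, group = group, min = q[1], q1 = q[2],
               median = q[3], q3 = q[4], max = q[5], mean = mean(v),
               n = length(v))
  }
  rbind(
    summarise(as.numeric(betweenness), "betweenness", "network"),
    summarise(as.numeric(betweenness)[path_nodes], "betweenness", "paths"),
    summarise(as.numeric(eigenvector), "eigenvector", "network"),
    summarise(as.numeric(eigenvector)[path_nodes], "eigenvector", "paths")
  )
}
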