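# Internal coordinate helpers. Trajectory coordinates follow the bio3d layout:
# one frame per row, columns (x1, y1, z1, x2, y2, z2, ...).

# xyz vector (length 3n) -> n x 3 matrix
vec2mat <- function(v) matrix(v, ncol = 3L, byrow = TRUE)

# n x 3 matrix -> xyz vector
mat2vec <- function(m) as.numeric(t(m))

# xyz column indices for atom indices
xyz_index <- function(atom_idx) {
  as.integer(rbind(3L * atom_idx - 2L, 3L * atom_idx - 1L, 3L * atom_idx))
}

# coordinates of frame i as an n x 3 matrix
frame_coords <- function(trajectory, i) {
  vec2mat(trajectory$xyz[i, ])
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a labelled numeric matrix as CSV
#'
#' Square matrices (DCCM, contact masks, edge-weight matrices) are written
#' with their row/column labels so they round-trip through [read_matrix_csv()].
#'
#' @param m numeric (or logical) matrix with dimnames.
#' @param path output file path.
#' @return invisibly, `path`.
#' @export
write_matrix_csv <- function(m, path) {
  df <- as.data.frame(m, check.names = FALSE)
  df <- cbind(label = rownames(m) %||% as.character(seq_len(nrow(m))), df)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a labelled matrix written by [write_matrix_csv()]
#'
#' @param path CSV file path.
#' @return numeric matrix with row/column labels restored.
#' @export
read_matrix_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- as.character(df[[1]])
  storage.mode(m) <- "double"
  m
}

# squared pairwise distance matrix between rows of m (n x 3)
pairdist2 <- function(m) {
  s <- rowSums(m * m)
  d2 <- outer(s, s, "+") - 2 * tcrossprod(m)
  d2[d2 < 0] <- 0
  d2
}

# Euclidean distance between two 3-vectors
dist3 <- function(a, b) sqrt(sum((a - b)^2))

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
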