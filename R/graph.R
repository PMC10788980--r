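#' Build a symmetric k-nearest-neighbor cell graph
#'
#' Edges connect each cell to its `k` nearest Euclidean neighbors in the
#' supplied (typically PCA) space, symmetrized by union: edge (i, j) exists
#' iff j is among i's k nearest neighbors or i among j's. Weights are binary,
#' the diagonal is zero. Exact duplicate points are resolved by index order,
#' never an error.
#'
#' @param pcs cells x d numeric matrix of coordinates.
#' @param k neighbors per cell, `1 <= k < cells`.
#' @return A `cello_graph` with the binary adjacency `A` (sparse, symmetric),
#'   the renormalized operator `A_norm` (see [normalize_adjacency()]), and the
#'   parameters `k`, `d`.
#' @export
build_knn_graph <- function(pcs, k = 15) {
  pcs <- as.matrix(pcs)
  n <- nrow(pcs)
  check_scalar(k, "k", lower = 1, integerish = TRUE)
  if (k >= n) stop_param("k (", k, ") must be < number of cells (", n, ")")
  nn <- RANN::nn2(pcs, pcs, k = min(k + 1L, n))
  idx <- nn$nn.idx
  # drop each point's self-match (kd-tree may not list self first under ties)
  neigh <- t(vapply(seq_len(n), function(i) {
    row <- idx[i, ]
    row <- row[row != i]
    row[seq_len(k)]
  }, integer(k)))
  if (k == 1L) neigh <- matrix(neigh, ncol = 1L)
  ii <- rep(seq_len(n), each = k)
  jj <- as.vector(t(neigh))
  A <- Matrix::sparseMatrix(i = ii, j = jj, x = 1, dims = c(n, n))
  A <- A + Matrix::t(A)
  A@x[] <- 1                       # union symmetrization, binary weights
  A <- Matrix::drop0(A)
  structure(list(A = A, A_norm = normalize_adjacency(A),
                 k = as.integer(k), d = ncol(pcs)),
            class = "cello_graph")
}

#' Self-looped symmetric degree normalization
#'
#' Computes the renormalized operator applied at each GCN layer:
#' with self-loops added, `A^ = A + I` and degree matrix `D^ = diag(rowSums(A^))`,
#' returns `D^(-1/2) A^ D^(-1/2)`. Entry (i, j) of the result is
#' `A^(i,j) / sqrt(d_i d_j)`; the diagonal is strictly positive and the
#' largest eigenvalue is exactly 1.
#'
#' @param A symmetric binary adjacency with zero diagonal (sparse or dense).
#' @return Sparse symmetric matrix of the same dimension.
#' @export
normalize_adjacency <- function(A) {
  A <- as(as(Matrix::Matrix(A, sparse = TRUE), "generalMatrix"),
          "CsparseMatrix")
  n <- nrow(A)
  if (n != ncol(A)) stop_param("adjacency must be square")
  if (any(Matrix::diag(A) != 0)) stop_param("adjacency must have zero diagonal")
  if (!Matrix::isSymmetric(A)) stop_param("adjacency must be symmetric")
  Ahat <- A + Matrix::Diagonal(n)
  dinv <- 1 / sqrt(Matrix::rowSums(Ahat))
  D <- Matrix::Diagonal(n, dinv)
  methods::as(D %*% Ahat %*% D, "CsparseMatrix")
}

#' Write a sparse graph as a plain-text triplet file
#'
#' One line per stored entry: `i j value` (1-based indices), for inspection
#' or downstream tooling.
#'
#' @param graph a `cello_graph` or sparse matrix.
#' @param path output file.
#' @param which `"A"` (binary adjacency) or `"A_norm"` (renormalized).
#' @return `path`, invisibly.
#' @export
write_graph_triplets <- function(graph, path, which = c("A", "A_norm")) {
  which <- match.arg(which)
  m <- if (inherits(graph, "cello_graph")) graph[[which]] else graph
  tr <- Matrix::summary(methods::as(m, "TsparseMatrix"))
  ord <- order(tr$i, tr$j)
  lines <- sprintf("%d %d %.10g", tr$i[ord], tr$j[ord], tr$x[ord])
  writeLines(lines, path)
  invisible(path)
}
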