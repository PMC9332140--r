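#' Exact k-nearest-neighbor graph
#'
#' Brute-force Euclidean kNN, computed in blocks so that the full n x n
#' distance matrix is never materialized. Self-neighbors are excluded and
#' distance ties are broken by ascending cell index, so the result is fully
#' deterministic.
#'
#' @param X cells x d numeric matrix (typically top principal components).
#' @param K number of neighbors (default 30); must satisfy `K < nrow(X)`.
#' @param block rows per block in the distance computation.
#' @return an object of class `NeighborGraph`: list with `indices`
#'   (cells x K), `distances` (cells x K, ascending per row) and `K`.
#' @export
knn_graph <- function(X, K = 30, block = 1024L) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (K <= 0) stop("K must be positive")
  if (K >= n) stop("K must be smaller than the number of points")
  sq <- rowSums(X^2)
  idx <- matrix(0L, n, K)
  dst <- matrix(0, n, K)
  for (start in seq(1L, n, by = block)) {
    rows <- start:min(start + block - 1L, n)
    # squared distances of this block against everything
    d2 <- outer(sq[rows], sq, "+") - 2 * tcrossprod(X[rows, , drop = FALSE], X)
    d2[d2 < 0] <- 0
    for (i in seq_along(rows)) {
      r <- rows[i]
      di <- d2[i, ]
      di[r] <- Inf                      # exclude self
      ord <- order(di, seq_len(n))[seq_len(K)]  # ties by ascending index
      idx[r, ] <- ord
      dst[r, ] <- sqrt(di[ord])
    }
  }
  structure(list(indices = idx, distances = dst, K = K),
            class = "NeighborGraph")
}

#' Query nearest neighbors of arbitrary points against a reference set
#'
#' @param X reference points (n x d); `Q` query points (m x d).
#' @param K neighbors per query.
#' @param exclude optional length-m integer vector; `exclude[i]` is a
#'   reference row forbidden for query i (used when a query is a perturbed
#'   copy of a reference cell).
#' @return list with `indices` (m x K) and `distances`.
#' @export
knn_query <- function(X, Q, K = 30, exclude = NULL) {
  X <- as.matrix(X); Q <- as.matrix(Q)
  n <- nrow(X); m <- nrow(Q)
  stopifnot(K <= n)
  sqx <- rowSums(X^2)
  idx <- matrix(0L, m, K); dst <- matrix(0, m, K)
  d2 <- outer(rowSums(Q^2), sqx, "+") - 2 * tcrossprod(Q, X)
  d2[d2 < 0] <- 0
  for (i in seq_len(m)) {
    di <- d2[i, ]
    if (!is.null(exclude) && !is.na(exclude[i])) di[exclude[i]] <- Inf
    ord <- order(di, seq_len(n))[seq_len(K)]
    idx[i, ] <- ord
    dst[i, ] <- sqrt(di[ord])
  }
  list(indices = idx, distances = dst)
}

#' Principal components used for neighborhood construction
#'
#' Thin wrapper around [stats::prcomp()] returning the pieces needed
#' elsewhere: cell coordinates, orthonormal gene loadings and the centering
#' vector, bundled as an `EmbeddingSpace`.
#'
#' @param M cells x genes matrix (typically normalized/log counts).
#' @param k number of components (default 30, capped by matrix rank).
#' @param name label for the embedding.
#' @return list with `coords` (cells x k), `loadings` Q (genes x k,
#'   orthonormal columns), `center` mu (length genes), `name`.
#' @export
pca_embedding <- function(M, k = 30, name = "pca") {
  M <- as.matrix(M)
  k <- min(k, nrow(M) - 1L, ncol(M))
  pc <- stats::prcomp(M, center = TRUE, scale. = FALSE, rank. = k)
  structure(list(coords = pc$x[, seq_len(k), drop = FALSE],
                 loadings = pc$rotation[, seq_len(k), drop = FALSE],
                 center = pc$center, name = name),
            class = "EmbeddingSpace")
}
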