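#' Neighborhood-smoothed moments of layer counts
#'
#' Dropout and counting noise are damped by replacing each cell's raw counts
#' with simple averages over its kNN neighborhood (the cell itself
#' included). First moments are computed for every present layer; second and
#' mixed moments for the layers needed by the generalized method-of-moments
#' estimators: `<u^2>`, `<s^2>`, `<us>` when unspliced/spliced data exist,
#' and `<l^2>`, `<r^2>`, `<lr>` when labeling data exist.
#'
#' @param lm a [layered_matrix()].
#' @param g a [knn_graph()] built on an embedding of the same cells.
#' @param groups optional per-cell labels (e.g. labeling time points):
#'   neighbors from a different group are dropped from each cell's
#'   averaging set, so moments never blend across labeling durations.
#'   Defaults to the labeling times for multi-time-point designs.
#' @return object of class `MomentSet`: list of cells x genes matrices named
#'   `m_<layer>` (first), `v_<layer>` (second, uncentered) and mixed
#'   `m_us` / `m_lr`.
#' @export
smooth_moments <- function(lm, g, groups = NULL) {
  stopifnot(inherits(lm, "LayeredMatrix"), inherits(g, "NeighborGraph"))
  n <- length(lm$cell_ids)
  stopifnot(nrow(g$indices) == n)
  if (is.null(groups) &&
      lm$experiment_type %in% c("kinetics", "degradation"))
    groups <- lm$label_time
  # adjacency including self, row-normalized after group filtering
  nb <- cbind(seq_len(n), g$indices)
  ii <- rep(seq_len(n), ncol(nb))
  jj <- as.vector(nb)
  if (!is.null(groups)) {
    stopifnot(length(groups) == n)
    keep <- groups[ii] == groups[jj]
    ii <- ii[keep]; jj <- jj[keep]
  }
  deg <- tabulate(ii, n)
  A <- Matrix::sparseMatrix(i = ii, j = jj, x = 1 / deg[ii], dims = c(n, n))
  avg <- function(M) {
    out <- as.matrix(A %*% M)
    dimnames(out) <- dimnames(M)
    out
  }
  out <- list()
  for (nm in names(lm$layers)) {
    out[[paste0("m_", nm)]] <- avg(lm$layers[[nm]])
    out[[paste0("v_", nm)]] <- avg(lm$layers[[nm]]^2)
  }
  if (all(c("u", "s") %in% names(lm$layers)))
    out$m_us <- avg(lm$layers$u * lm$layers$s)
  if (all(c("l", "r") %in% names(lm$layers)))
    out$m_lr <- avg(lm$layers$l * lm$layers$r)
  out$n_cells <- n
  out$gene_ids <- lm$gene_ids
  structure(out, class = "MomentSet")
}
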