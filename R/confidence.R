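#' Cell-wise confidence of velocity vectors
#'
#' `jaccard` scores each cell by how much its neighborhood is preserved
#' when the cell is displaced by its own velocity: the Jaccard index
#' between the K-nearest-neighbor set of `x_i` and that of `x_i + v_i`
#' (both queried against the observed states). Velocities consistent with
#' the local manifold barely change the neighbor set (J near 1); wildly
#' inconsistent ones yield disjoint sets (J near 0). `cosine` and
#' `correlation` instead score the agreement of `v_i` with the velocities
#' of its neighbors.
#'
#' @param X cells x d states; `V` same-shape velocities.
#' @param g a [knn_graph()] on `X` (its `K` sets the neighborhood size).
#' @param method `"jaccard"`, `"cosine"` or `"correlation"`.
#' @return numeric per-cell confidence scores.
#' @export
cell_velocity_confidence <- function(X, V, g,
                                     method = c("jaccard", "cosine",
                                                "correlation")) {
  method <- match.arg(method)
  X <- as.matrix(X); V <- as.matrix(V)
  stopifnot(all(dim(X) == dim(V)), inherits(g, "NeighborGraph"))
  n <- nrow(X)
  if (method == "jaccard") {
    cur <- g$indices
    fut <- knn_query(X, X + V, K = g$K, exclude = seq_len(n))$indices
    vapply(seq_len(n), function(i) {
      a <- cur[i, ]; b <- fut[i, ]
      length(intersect(a, b)) / length(union(a, b))
    }, numeric(1))
  } else {
    vapply(seq_len(n), function(i) {
      nb <- g$indices[i, ]
      vi <- V[i, ]
      sims <- apply(V[nb, , drop = FALSE], 1, function(vj) {
        if (method == "cosine") {
          den <- sqrt(sum(vi^2)) * sqrt(sum(vj^2))
          if (den == 0) return(NA_real_)
          sum(vi * vj) / den
        } else {
          if (stats::sd(vi) == 0 || stats::sd(vj) == 0) return(NA_real_)
          stats::cor(vi, vj)
        }
      })
      mean(sims, na.rm = TRUE)
    }, numeric(1))
  }
}

#' Gene-wise velocity confidence from lineage priors
#'
#' Given progenitor and terminal cell groups, each gene is classified as
#' induced (median expression rises from progenitor to terminal) or
#' repressed (it falls) for every progenitor-terminal pair. An induced gene
#' should have non-negative velocity in the cells of both groups (up to a
#' small tolerance), a repressed gene non-positive velocity. The confidence
#' for a gene and pair is 1 minus the fraction of cells violating this sign
#' constraint; genes whose minimum confidence across pairs exceeds
#' `threshold` are retained. Genes with no detectable expression shift have
#' undefined phase and missing (not zero) confidence.
#'
#' @param expr cells x genes expression matrix (moments or normalized).
#' @param velocity cells x genes velocity matrix.
#' @param group per-cell group labels.
#' @param progenitor_groups,terminal_groups group labels defining lineage
#'   direction.
#' @param tolerance violation tolerance as a fraction of the per-gene
#'   velocity scale (default 0.05; the scale is the maximum absolute
#'   velocity over the cells of the pair).
#' @param threshold retention cutoff on the minimum confidence (default 0.8).
#' @return list with `confidence` (genes x pairs matrix), `phase`
#'   (+1 induction / -1 repression / NA flat), `retained` (gene ids).
#' @export
gene_velocity_confidence <- function(expr, velocity, group,
                                     progenitor_groups, terminal_groups,
                                     tolerance = 0.05, threshold = 0.8) {
  expr <- as.matrix(expr); velocity <- as.matrix(velocity)
  group <- as.character(group)
  unknown <- setdiff(c(progenitor_groups, terminal_groups), unique(group))
  if (length(unknown))
    stop("unknown group label(s): ", paste(unknown, collapse = ", "))
  pairs <- expand.grid(progenitor = progenitor_groups,
                       terminal = terminal_groups,
                       stringsAsFactors = FALSE)
  gn <- colnames(expr)
  if (is.null(gn)) gn <- sprintf("gene_%d", seq_len(ncol(expr)))
  conf <- matrix(NA_real_, ncol(expr), nrow(pairs),
                 dimnames = list(gn, paste(pairs$progenitor, pairs$terminal,
                                           sep = "->")))
  phase <- conf
  for (p in seq_len(nrow(pairs))) {
    prog <- group == pairs$progenitor[p]
    term <- group == pairs$terminal[p]
    cells <- prog | term
    for (j in seq_len(ncol(expr))) {
      shift <- stats::median(expr[term, j]) - stats::median(expr[prog, j])
      if (shift == 0) next  # flat gene: phase undefined, confidence missing
      ph <- sign(shift)
      v <- velocity[cells, j]
      scale <- max(abs(v))
      tol <- tolerance * scale
      violating <- if (ph > 0) v < -tol else v > tol
      conf[j, p] <- 1 - mean(violating)
      phase[j, p] <- ph
    }
  }
  min_conf <- apply(conf, 1, function(x)
    if (all(is.na(x))) NA_real_ else min(x, na.rm = TRUE))
  list(confidence = conf, phase = phase,
       retained = gn[!is.na(min_conf) & min_conf > threshold])
}
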