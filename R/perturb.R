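#' In-silico genetic perturbation through the vector-field Jacobian
#'
#' A finite expression perturbation `delta_y` (gene space, e.g. a large
#' negative value for a suppressed transcription factor) is mapped to the
#' field's PCA space as `delta_x = c * Q' (delta_y - mu)` (the transform is
#' applied exactly in this centered form; set `centered = FALSE` to skip the
#' mean subtraction), propagated through the exact differential
#' `delta_f = J(x) delta_x` at every queried cell, and mapped back to gene
#' space as `delta_g = Q delta_f + mu`. The (state, response) pairs play the
#' same role as (state, velocity) pairs and can be fed to any downstream
#' flow analysis.
#'
#' @param model field fitted in the embedding's coordinate space.
#' @param emb a [pca_embedding()] (or list with `loadings` Q and `center`
#'   mu); `Q` rows must be named by gene when `delta_y` is named.
#' @param delta_y gene-space perturbation: named numeric vector (unnamed
#'   genes are 0) or full-length vector.
#' @param X_cells cells x d states in field space at which to evaluate
#'   (default: the model's training states).
#' @param c amplification constant (default 1).
#' @param centered subtract `mu` inside the forward transform (default TRUE,
#'   as printed in the defining transform).
#' @return object of class `PerturbationResult`: list with `delta_x`,
#'   `delta_f` (cells x d), `delta_g` (cells x genes), `X` (the states).
#' @export
perturb <- function(model, emb, delta_y, X_cells = NULL, c = 1,
                    centered = TRUE) {
  Q <- as.matrix(emb$loadings)
  mu <- emb$center
  if (is.null(mu)) mu <- rep(0, nrow(Q))
  if (!is.null(names(delta_y)) && length(delta_y) != nrow(Q)) {
    missing <- setdiff(names(delta_y), rownames(Q))
    if (length(missing))
      stop("perturbed gene(s) absent from loadings: ",
           paste(missing, collapse = ", "))
    dy <- rep(0, nrow(Q))
    names(dy) <- rownames(Q)
    dy[names(delta_y)] <- delta_y
    delta_y <- dy
  }
  stopifnot(length(delta_y) == nrow(Q))
  if (is.null(X_cells)) X_cells <- model$X
  X_cells <- as.matrix(X_cells)
  dy_eff <- if (centered) delta_y - mu else delta_y
  delta_x <- c * drop(crossprod(Q, dy_eff))
  J <- vf_jacobian(model, X_cells)
  n <- nrow(X_cells)
  delta_f <- t(vapply(seq_len(n), function(i) drop(J[, , i] %*% delta_x),
                      numeric(ncol(X_cells))))
  delta_g <- sweep(delta_f %*% t(Q), 2, mu, "+")
  colnames(delta_g) <- rownames(Q)
  structure(list(delta_x = delta_x, delta_f = delta_f, delta_g = delta_g,
                 X = X_cells, c = c, centered = centered),
            class = "PerturbationResult")
}

#' @exportS3Method print PerturbationResult
print.PerturbationResult <- function(x, ...) {
  cat(sprintf(
    "PerturbationResult: %d cells, |delta_x| = %.4g, c = %.3g\n",
    nrow(x$X), sqrt(sum(x$delta_x^2)), x$c))
  invisible(x)
}
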