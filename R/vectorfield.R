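#' Data-driven inverse bandwidth for the Gaussian kernel
#'
#' The kernel width follows the local density of the state samples: with
#' K-nearest neighborhoods of `round(neighbor_fraction * n)` cells (at
#' least 2), `d_m` is the grand mean of each point's mean neighbor
#' distance, and the inverse bandwidth is `w = 1.5 / (2 d_m)` so that the
#' kernel standard deviation is `d_m / 1.5`.
#'
#' @param X n x d state matrix.
#' @param neighbor_fraction fraction of points per neighborhood (default 0.2).
#' @return inverse bandwidth `w` (attribute `d_m` carries the distance).
#' @export
default_bandwidth <- function(X, neighbor_fraction = 0.2) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (n < 2) stop("need at least two points")
  K <- min(max(2L, round(neighbor_fraction * n)), n - 1L)
  g <- knn_graph(X, K = K)
  d_m <- mean(rowMeans(g$distances))
  if (d_m == 0) stop("all points identical: bandwidth undefined")
  structure(1.5 / (2 * d_m), d_m = d_m)
}

gauss_kernel <- function(A, B, w) {
  # exp(-w * ||a - b||^2) for all row pairs; A n x d, B m x d
  d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * tcrossprod(A, B)
  d2[d2 < 0] <- 0
  exp(-w * d2)
}

#' Sparse kernel reconstruction of a velocity vector field
#'
#' Learns a continuous vector-valued function `f(x) = sum_j Gamma(x, ctrl_j)
#' c_j` (isotropic Gaussian kernel `Gamma(x, y) = exp(-w ||x - y||^2)`) from
#' sampled (state, velocity) pairs by sparse vector-field consensus:
#' inlier velocities are modeled as `f(x) + Gaussian noise (sigma^2)`,
#' outliers as uniform over a volume `a`, and an EM loop alternates between
#' the inlier posterior `p_i` (E-step) and the regularized kernel regression
#' `(U'PU + lambda sigma^2 K) C = U'PV` plus updates
#' `sigma^2 = sum_i p_i ||v_i - f(x_i)||^2 / (d tr P)` and `q = trP / n`
#' (M-step). The objective is
#' `Phi = 1/(2 sigma^2) sum_i p_i ||v_i - f(x_i)||^2 + lambda/2 ||f||_H^2`
#' with `||f||_H^2 = sum_ij c_i' K_ij c_j`.
#'
#' @param X n x d states; `V` n x d velocities.
#' @param m number of control points (default `max(50, 5%)` of n, capped at
#'   n), drawn uniformly without replacement.
#' @param lambda regularization coefficient (default 3).
#' @param w inverse bandwidth; `NULL` uses [default_bandwidth()].
#' @param a outlier-domain volume; `NULL` uses the product of per-dimension
#'   velocity ranges.
#' @param q_init initial inlier fraction (default 0.9).
#' @param max_iter,tol EM controls (500, 1e-5 relative loss change).
#' @param seed seed for the control-point draw.
#' @param space label recording which space the samples live in.
#' @return object of class `VectorFieldModel` with elements `ctrl` (m x d),
#'   `C` (m x d coefficients), `w`, `lambda`, `sigma2`, `q`, `p`
#'   (per-sample inlier posterior), `a`, `loss_trace`, `X`, `V`.
#' @seealso [predict.VectorFieldModel()], [vf_jacobian()], [detect_outliers()]
#' @export
fit_vectorfield <- function(X, V, m = NULL, lambda = 3, w = NULL, a = NULL,
                            q_init = 0.9, max_iter = 500, tol = 1e-5,
                            seed = 0, space = "unknown") {
  X <- as.matrix(X); V <- as.matrix(V)
  stopifnot(all(dim(X) == dim(V)), all(is.finite(X)), all(is.finite(V)))
  n <- nrow(X); d <- ncol(X)
  if (is.null(m)) m <- max(50L, ceiling(0.05 * n))
  m <- min(m, n)
  stopifnot(m >= 1)
  if (is.null(w)) w <- as.numeric(default_bandwidth(X))
  stopifnot(w > 0)
  set.seed(seed)
  ctrl_idx <- sample.int(n, m)
  ctrl <- X[ctrl_idx, , drop = FALSE]
  if (is.null(a)) {
    ranges <- apply(V, 2, function(col) diff(range(col)))
    ranges[ranges == 0] <- 1
    a <- prod(ranges)
  }
  U <- gauss_kernel(X, ctrl, w)        # n x m
  K <- gauss_kernel(ctrl, ctrl, w)     # m x m Gram
  # Cholesky factor of K for the penalty rows of the augmented least squares
  # (solving by QR keeps the conditioning at cond(U), not cond(U)^2)
  R_K <- chol(K + diag(1e-10, m))
  C <- matrix(0, m, d)
  F_hat <- U %*% C
  sigma2 <- mean(rowSums(V^2)) / d
  q <- q_init
  loss_trace <- numeric(0)   # EM objective: negative penalized log-likelihood
  phi_trace <- numeric(0)    # weighted residual objective Phi
  loss_old <- Inf
  for (iter in seq_len(max_iter)) {
    # E-step: inlier posterior from the previous iteration's field
    res2 <- rowSums((V - F_hat)^2)
    g_in <- exp(-res2 / (2 * sigma2))
    p <- g_in / (g_in + (1 - q) / q * (2 * pi * sigma2)^(d / 2) / a)
    p[!is.finite(p)] <- 0
    # M-step: weighted regularized kernel regression for C, solved as the
    # augmented least squares [sqrt(p) U; sqrt(lambda sigma^2) R_K] C =
    # [sqrt(p) V; 0] (equivalent to (U'PU + lambda sigma^2 K) C = U'PV)
    sp <- sqrt(p)
    Aug <- rbind(U * sp, sqrt(lambda * sigma2) * R_K)
    Baug <- rbind(V * sp, matrix(0, m, d))
    C <- tryCatch(qr.coef(qr(Aug, LAPACK = TRUE), Baug), error = function(e) {
      warning("singular normal equations; adding ridge jitter 1e-8")
      solve(crossprod(U, U * p) + lambda * sigma2 * K + diag(1e-8, m),
            crossprod(U, V * p))
    })
    F_hat <- U %*% C
    res2 <- rowSums((V - F_hat)^2)
    reg <- lambda / 2 * sum(C * (K %*% C))
    # Phi with the sigma^2 that entered this solve (C minimizes it exactly)
    phi <- sum(p * res2) / (2 * sigma2) + reg
    # remaining M-step coordinate updates
    trP <- sum(p)
    sigma2 <- max(sum(p * res2) / (d * max(trP, 1e-12)), 1e-12)
    q <- min(max(trP / n, 1e-6), 1)   # q = 1: uniform component vanishes
    # EM descends the negative penalized marginal log-likelihood; Phi is
    # rescaled by the sigma^2 update each iteration and is not monotone
    dens <- q * (2 * pi * sigma2)^(-d / 2) * exp(-res2 / (2 * sigma2)) +
      (1 - q) / a
    loss <- -sum(log(pmax(dens, .Machine$double.xmin))) + reg
    if (!is.finite(loss) || !is.finite(phi))
      stop("non-finite loss at iteration ", iter)
    loss_trace <- c(loss_trace, loss)
    phi_trace <- c(phi_trace, phi)
    if (is.finite(loss_old) &&
        abs(loss - loss_old) < tol * max(abs(loss_old), 1e-12)) break
    loss_old <- loss
  }
  structure(
    list(ctrl = ctrl, C = C, w = w, lambda = lambda, sigma2 = sigma2,
         q = q, p = p, a = a, loss_trace = loss_trace,
         phi_trace = phi_trace, n_iter = iter,
         d = d, space = space, X = X, V = V, ctrl_idx = ctrl_idx,
         version = 1L),
    class = "VectorFieldModel")
}

#' Evaluate the fitted vector field
#'
#' @param object a [fit_vectorfield()] model.
#' @param newdata query states (vector of length d or matrix n x d);
#'   defaults to the training states.
#' @param ... unused.
#' @return matrix of velocities, one row per query.
#' @exportS3Method predict VectorFieldModel
predict.VectorFieldModel <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) newdata <- object$X
  if (is.null(dim(newdata))) newdata <- matrix(newdata, nrow = 1)
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != object$d)
    stop("query dimension ", ncol(newdata), " != model dimension ", object$d)
  gauss_kernel(newdata, object$ctrl, object$w) %*% object$C
}

#' @exportS3Method print VectorFieldModel
print.VectorFieldModel <- function(x, ...) {
  cat(sprintf(
    "VectorFieldModel (%s space): %d samples, %d control points, d = %d\n",
    x$space, nrow(x$X), nrow(x$ctrl), x$d))
  cat(sprintf(
    "  w = %.4g, lambda = %.3g, sigma2 = %.4g, inlier fraction q = %.3f\n",
    x$w, x$lambda, x$sigma2, x$q))
  cat(sprintf("  EM: %d iterations, final loss %.6g\n",
              x$n_iter, utils::tail(x$loss_trace, 1)))
  invisible(x)
}

#' @exportS3Method summary VectorFieldModel
summary.VectorFieldModel <- function(object, ...) {
  print(object)
  res <- residuals(object)
  speed <- sqrt(rowSums(predict(object)^2))
  cat(sprintf("  residual speed: median %.4g (data speed median %.4g)\n",
              stats::median(sqrt(rowSums(res^2))),
              stats::median(sqrt(rowSums(object$V^2)))))
  cat(sprintf("  inliers (p >= 0.5): %d / %d\n",
              sum(object$p >= 0.5), length(object$p)))
  invisible(object)
}

#' @exportS3Method coef VectorFieldModel
coef.VectorFieldModel <- function(object, ...) {
  object$C
}

#' @exportS3Method residuals VectorFieldModel
residuals.VectorFieldModel <- function(object, ...) {
  object$V - predict(object)
}

#' Training-sample inlier mask from the EM posterior
#'
#' @param model a fitted [fit_vectorfield()] model.
#' @param cutoff posterior cutoff (default 0.5).
#' @return logical vector, `TRUE` for inliers; the posterior itself is in
#'   `model$p`.
#' @export
detect_outliers <- function(model, cutoff = 0.5) {
  stopifnot(inherits(model, "VectorFieldModel"))
  model$p >= cutoff
}

#' Simulate trajectories in the fitted field
#'
#' Integrates the deterministic field forward from initial states (see
#' [vf_trajectory()]); one trajectory per row of `x0`.
#'
#' @param object a `VectorFieldModel`.
#' @param nsim number of trajectories when `x0` is not given (sampled from
#'   the training states).
#' @param seed RNG seed for sampling initial states.
#' @param x0 matrix of initial states (overrides `nsim`).
#' @param t_final,n_steps integration horizon and output resolution.
#' @param ... unused.
#' @return list of `Trajectory` objects.
#' @exportS3Method simulate VectorFieldModel
simulate.VectorFieldModel <- function(object, nsim = 1, seed = NULL,
                                      x0 = NULL, t_final = 10,
                                      n_steps = 200, ...) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(x0)) {
    idx <- sample.int(nrow(object$X), nsim, replace = nsim > nrow(object$X))
    x0 <- object$X[idx, , drop = FALSE]
  }
  if (is.null(dim(x0))) x0 <- matrix(x0, nrow = 1)
  lapply(seq_len(nrow(x0)), function(i)
    vf_trajectory(object, x0[i, ], t_final = t_final, n_steps = n_steps))
}

#' Streamline-style plot of a 2D vector field model
#'
#' Draws the training states, arrows for the fitted field on a regular
#' grid, and marks outliers.
#'
#' @param x a 2D `VectorFieldModel`.
#' @param grid_n grid resolution per axis.
#' @param scale arrow scale factor.
#' @param ... passed to [graphics::plot()].
#' @exportS3Method plot VectorFieldModel
plot.VectorFieldModel <- function(x, grid_n = 15, scale = NULL, ...) {
  stopifnot(x$d == 2)
  X <- x$X
  graphics::plot(X[, 1], X[, 2], col = ifelse(x$p >= 0.5, "grey60", "red"),
                 pch = 16, cex = 0.4, xlab = "dim 1", ylab = "dim 2", ...)
  gx <- seq(min(X[, 1]), max(X[, 1]), length.out = grid_n)
  gy <- seq(min(X[, 2]), max(X[, 2]), length.out = grid_n)
  G <- as.matrix(expand.grid(gx, gy))
  Vg <- predict(x, G)
  if (is.null(scale)) {
    sp <- sqrt(rowSums(Vg^2))
    scale <- 0.5 * min(diff(gx)[1], diff(gy)[1]) / max(stats::median(sp), 1e-12)
  }
  graphics::arrows(G[, 1], G[, 2], G[, 1] + scale * Vg[, 1],
                   G[, 2] + scale * Vg[, 2], length = 0.04, col = "steelblue")
  invisible(x)
}

#' Save / load a fitted vector-field model
#'
#' Lossless single-archive serialization: control points, coefficients,
#' bandwidth and EM state round-trip bit-for-bit. Files carry a format
#' version; loading a different version raises an incompatibility error.
#'
#' @param model a `VectorFieldModel`.
#' @param path archive path.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "VectorFieldModel"))
  saveRDS(list(format = "dynofield-vectorfield", version = model$version,
               model = unclass(model)), path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  obj <- tryCatch(readRDS(path), error = function(e)
    stop("cannot parse model archive: ", conditionMessage(e)))
  if (!is.list(obj) || !identical(obj$format, "dynofield-vectorfield"))
    stop("not a dynofield vector-field archive")
  if (!identical(obj$version, 1L))
    stop("incompatible model archive version: ", obj$version)
  structure(obj$model, class = "VectorFieldModel")
}
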