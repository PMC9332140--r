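#' Wrap a plain function (and optional Jacobian) as a vector field
#'
#' Lets the topology, geometry and path machinery run on analytically known
#' fields (e.g. the toggle-switch benchmark) exactly as on fitted models.
#'
#' @param f function taking a state matrix (n x d) and returning velocities
#'   (n x d).
#' @param jacobian optional function taking one state (length-d vector) and
#'   returning the d x d Jacobian; central finite differences are used when
#'   absent.
#' @param d state dimension.
#' @return object of class `FunctionField`.
#' @export
as_vectorfield <- function(f, jacobian = NULL, d) {
  structure(list(f = f, jac = jacobian, d = d), class = "FunctionField")
}

#' @exportS3Method predict FunctionField
predict.FunctionField <- function(object, newdata, ...) {
  if (is.null(dim(newdata))) newdata <- matrix(newdata, nrow = 1)
  object$f(as.matrix(newdata))
}

#' Analytical Jacobian of a vector field
#'
#' For a kernel model `f(x) = sum_j Gamma(x, ctrl_j) c_j` the Jacobian is
#' available in closed form:
#' `J(x) = -2 w sum_j Gamma(x, ctrl_j) c_j (x - ctrl_j)' = -2 w C' K D`,
#' with `K = diag(Gamma(x, ctrl_j))` and `D` the matrix of rows
#' `x - ctrl_j`. Entry `J[i, j] = d f_i / d x_j`.
#'
#' @param model a `VectorFieldModel` or [as_vectorfield()] wrapper.
#' @param X query states (n x d matrix or length-d vector).
#' @return d x d x n array of Jacobians.
#' @export
vf_jacobian <- function(model, X) UseMethod("vf_jacobian")

#' @export
vf_jacobian.VectorFieldModel <- function(model, X) {
  if (is.null(dim(X))) X <- matrix(X, nrow = 1)
  X <- as.matrix(X)
  stopifnot(ncol(X) == model$d)
  n <- nrow(X); d <- model$d
  Gam <- gauss_kernel(X, model$ctrl, model$w)  # n x m
  J <- array(0, c(d, d, n))
  for (i in seq_len(n)) {
    D <- sweep(model$ctrl, 2, X[i, ], "-") * -1   # rows x - ctrl_j
    J[, , i] <- -2 * model$w * crossprod(model$C, Gam[i, ] * D)
  }
  J
}

#' @export
vf_jacobian.FunctionField <- function(model, X) {
  if (is.null(dim(X))) X <- matrix(X, nrow = 1)
  X <- as.matrix(X)
  n <- nrow(X); d <- model$d
  J <- array(0, c(d, d, n))
  for (i in seq_len(n)) {
    J[, , i] <- if (!is.null(model$jac)) model$jac(X[i, ]) else
      numeric_jacobian(function(x) drop(predict(model, x)), X[i, ])
  }
  J
}

# central finite-difference Jacobian (oracle for the analytic formula)
numeric_jacobian <- function(f, x, h = 1e-5) {
  d <- length(x)
  f0 <- f(x)
  J <- matrix(0, length(f0), d)
  for (j in seq_len(d)) {
    e <- rep(0, d); e[j] <- h
    J[, j] <- (f(x + e) - f(x - e)) / (2 * h)
  }
  J
}

#' Differential-geometry quantities of a vector field
#'
#' Per query point: divergence `trace(J)`; curl (scalar
#' `dF2/dx1 - dF1/dx2` in 2D, the standard 3-vector in 3D); acceleration
#' `a = J v` (the time derivative of velocity along the streamline); and
#' the curvature vector
#' `kappa = (Jv (v.v) - v (v.Jv)) / ||v||^4` (the derivative of the unit
#' tangent scaled by 1/||v||). In 2D the equivalent triple-product form
#' `v x (Jv x v) / ||v||^4` is also computed and asserted to agree.
#' Curvature at a zero-velocity point is undefined and reported as `NA`.
#'
#' @param model a `VectorFieldModel` or `FunctionField`.
#' @param X query states (n x d).
#' @param V optional velocities at `X`; evaluated from the model if absent.
#' @return object of class `GeometryFields`: list with `jacobian`
#'   (d x d x n), `divergence`, `curl`, `acceleration`, `curvature`,
#'   `speed`.
#' @export
vf_geometry <- function(model, X, V = NULL) {
  if (is.null(dim(X))) X <- matrix(X, nrow = 1)
  X <- as.matrix(X)
  n <- nrow(X); d <- ncol(X)
  if (is.null(V)) V <- predict(model, X)
  V <- as.matrix(V)
  J <- vf_jacobian(model, X)
  divergence <- vapply(seq_len(n), function(i) sum(diag(J[, , i])),
                       numeric(1))
  curl <- NULL
  if (d == 2) {
    curl <- vapply(seq_len(n), function(i) J[2, 1, i] - J[1, 2, i],
                   numeric(1))
  } else if (d == 3) {
    curl <- t(vapply(seq_len(n), function(i) {
      Ji <- J[, , i]
      c(Ji[3, 2] - Ji[2, 3], Ji[1, 3] - Ji[3, 1], Ji[2, 1] - Ji[1, 2])
    }, numeric(3)))
  }
  acceleration <- t(vapply(seq_len(n), function(i) drop(J[, , i] %*% V[i, ]),
                           numeric(d)))
  curvature <- matrix(NA_real_, n, d)
  for (i in seq_len(n)) {
    v <- V[i, ]
    nv2 <- sum(v^2)
    if (nv2 == 0) next
    Jv <- drop(J[, , i] %*% v)
    kappa <- (Jv * nv2 - v * sum(v * Jv)) / nv2^2
    if (d == 2) {
      # triple-product form via 3D embedding: v x (Jv x v) / ||v||^4
      v3 <- c(v, 0); Jv3 <- c(Jv, 0)
      kappa2 <- cross3(v3, cross3(Jv3, v3))[1:2] / nv2^2
      if (max(abs(kappa - kappa2)) > 1e-8 * max(1, max(abs(kappa))))
        stop("curvature forms disagree: numerical inconsistency")
    }
    curvature[i, ] <- kappa
  }
  structure(list(jacobian = J, divergence = divergence, curl = curl,
                 acceleration = acceleration, curvature = curvature,
                 speed = sqrt(rowSums(V^2))),
            class = "GeometryFields")
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Project a field-space Jacobian into gene space
#'
#' For a field learned in a PCA space with orthonormal loadings `Q`
#' (genes x k), the gene-space regulatory Jacobian is `G = Q J Q'`; entry
#' `G[i, j]` is the sensitivity of gene i's velocity to gene j's
#' expression. Only the requested (effector, regulator) pairs are computed,
#' so the full genes x genes matrix is never materialized for large gene
#' sets.
#'
#' @param J d x d x n Jacobian array in field space (k = d components).
#' @param Q genes x k loading matrix (rows named by gene).
#' @param pairs two-column matrix / data.frame of (effector, regulator)
#'   gene ids or indices; `NULL` computes the full matrix (small gene sets
#'   only).
#' @return if `pairs` given: n x npairs matrix of per-cell entries;
#'   else genes x genes x n array.
#' @export
project_jacobian <- function(J, Q, pairs = NULL) {
  Q <- as.matrix(Q)
  n <- dim(J)[3]
  if (is.null(pairs)) {
    G <- array(0, c(nrow(Q), nrow(Q), n),
               dimnames = list(rownames(Q), rownames(Q), NULL))
    for (i in seq_len(n)) G[, , i] <- Q %*% J[, , i] %*% t(Q)
    return(G)
  }
  pairs <- as.matrix(pairs)
  resolve <- function(g) {
    if (is.character(g)) {
      idx <- match(g, rownames(Q))
      if (anyNA(idx)) stop("gene(s) not in loadings: ",
                           paste(g[is.na(idx)], collapse = ", "))
      idx
    } else as.integer(g)
  }
  eff <- resolve(pairs[, 1]); reg <- resolve(pairs[, 2])
  out <- matrix(0, n, nrow(pairs))
  colnames(out) <- paste(pairs[, 1], pairs[, 2], sep = "~")
  for (i in seq_len(n)) {
    Ji <- J[, , i]
    for (p in seq_along(eff))
      out[i, p] <- drop(Q[eff[p], , drop = FALSE] %*% Ji %*% Q[reg[p], ])
  }
  out
}

#' Rank genes by a per-cell quantity, per cluster
#'
#' Averages any cells x genes quantity (expression, velocity, acceleration,
#' curvature component, ...) within each cluster -- raw or absolute values
#' -- and ranks genes per cluster in descending order, ties broken by gene
#' identifier.
#'
#' @param Q_matrix cells x genes matrix.
#' @param clusters per-cell labels (a single label ranks across all cells).
#' @param mode `"raw"` or `"abs"`.
#' @return object of class `RankingTable`: long data.frame with columns
#'   `cluster`, `gene`, `mean`, `rank`.
#' @export
rank_quantity <- function(Q_matrix, clusters = NULL, mode = c("raw", "abs")) {
  mode <- match.arg(mode)
  Q_matrix <- as.matrix(Q_matrix)
  gn <- colnames(Q_matrix)
  if (is.null(gn)) gn <- sprintf("gene_%d", seq_len(ncol(Q_matrix)))
  if (is.null(clusters)) clusters <- rep("all", nrow(Q_matrix))
  clusters <- as.factor(clusters)
  empty <- setdiff(levels(clusters), unique(as.character(clusters)))
  if (length(empty)) warning("empty cluster(s) excluded: ",
                             paste(empty, collapse = ", "))
  M <- if (mode == "abs") abs(Q_matrix) else Q_matrix
  out <- do.call(rbind, lapply(unique(levels(droplevels(clusters))),
                               function(cl) {
    mu <- colMeans(M[clusters == cl, , drop = FALSE])
    ord <- order(-mu, gn)
    data.frame(cluster = cl, gene = gn[ord], mean = mu[ord],
               rank = seq_along(mu), row.names = NULL,
               stringsAsFactors = FALSE)
  }))
  class(out) <- c("RankingTable", "data.frame")
  out
}

#' Regulatory rankings from an averaged gene-space Jacobian
#'
#' Five views of a (cluster-)averaged Jacobian `<J>` (effectors in rows,
#' regulators in columns): `interactions` ranks all entries; `regulators`
#' ranks each row (top regulators per effector); `effectors` ranks each
#' column (top effectors per regulator); `top_regulators` ranks the row
#' sums `R_z = sum_x <J[z, x]>`; `top_effectors` ranks the column sums
#' `E_x = sum_z <J[z, x]>`.
#'
#' @param Jbar averaged genes x genes Jacobian (rows = effectors), or a
#'   genes x genes x cells array which is averaged first.
#' @param mode one of `"interactions"`, `"regulators"`, `"effectors"`,
#'   `"top_regulators"`, `"top_effectors"`.
#' @param use_abs rank by absolute value.
#' @return a `RankingTable` data.frame.
#' @export
rank_jacobian <- function(Jbar, mode = c("interactions", "regulators",
                                         "effectors", "top_regulators",
                                         "top_effectors"),
                          use_abs = TRUE) {
  mode <- match.arg(mode)
  if (length(dim(Jbar)) == 3) Jbar <- apply(Jbar, c(1, 2), mean)
  gn <- rownames(Jbar)
  if (is.null(gn)) gn <- sprintf("gene_%d", seq_len(nrow(Jbar)))
  score <- function(x) if (use_abs) abs(x) else x
  out <- switch(mode,
    interactions = {
      idx <- as.matrix(expand.grid(effector = seq_along(gn),
                                   regulator = seq_along(gn)))
      val <- Jbar[idx]
      ord <- order(-score(val), gn[idx[, 1]], gn[idx[, 2]])
      data.frame(effector = gn[idx[ord, 1]], regulator = gn[idx[ord, 2]],
                 value = val[ord], rank = seq_along(val),
                 stringsAsFactors = FALSE)
    },
    regulators = do.call(rbind, lapply(seq_along(gn), function(z) {
      ord <- order(-score(Jbar[z, ]), gn)
      data.frame(effector = gn[z], regulator = gn[ord],
                 value = Jbar[z, ord], rank = seq_along(gn),
                 stringsAsFactors = FALSE)
    })),
    effectors = do.call(rbind, lapply(seq_along(gn), function(x) {
      ord <- order(-score(Jbar[, x]), gn)
      data.frame(regulator = gn[x], effector = gn[ord],
                 value = Jbar[ord, x], rank = seq_along(gn),
                 stringsAsFactors = FALSE)
    })),
    top_regulators = {
      s <- rowSums(Jbar)
      ord <- order(-score(s), gn)
      data.frame(gene = gn[ord], value = s[ord], rank = seq_along(s),
                 stringsAsFactors = FALSE)
    },
    top_effectors = {
      s <- colSums(Jbar)
      ord <- order(-score(s), gn)
      data.frame(gene = gn[ord], value = s[ord], rank = seq_along(s),
                 stringsAsFactors = FALSE)
    })
  class(out) <- c("RankingTable", "data.frame")
  out
}

#' Score mutually inhibiting (toggle-switch) gene pairs
#'
#' For each cell's gene-space Jacobian `J`, computes `K = J J'` and gates
#' it by mutual inhibition with Iverson brackets:
#' `L[i, j] = K[i, j] [J[i, j] < 0] [J[j, i] < 0]`. Pair scores are the
#' cell-averaged absolute `L`; the upper triangle is ranked descending.
#'
#' @param J genes x genes x cells Jacobian array (gene space).
#' @return a `RankingTable` data.frame of pairs with `score` and `rank`.
#' @export
toggle_pairs <- function(J) {
  stopifnot(length(dim(J)) == 3)
  g <- dim(J)[1]; n <- dim(J)[3]
  gn <- dimnames(J)[[1]]
  if (is.null(gn)) gn <- sprintf("gene_%d", seq_len(g))
  acc <- matrix(0, g, g)
  for (i in seq_len(n)) {
    Ji <- J[, , i]
    K <- tcrossprod(Ji)
    L <- K * (Ji < 0) * (t(Ji) < 0)
    acc <- acc + abs(L)
  }
  acc <- acc / n
  ut <- which(upper.tri(acc), arr.ind = TRUE)
  val <- acc[ut]
  ord <- order(-val, gn[ut[, 1]], gn[ut[, 2]])
  out <- data.frame(gene1 = gn[ut[ord, 1]], gene2 = gn[ut[ord, 2]],
                    score = val[ord], rank = seq_along(val),
                    stringsAsFactors = FALSE)
  class(out) <- c("RankingTable", "data.frame")
  out
}

# derivative of the activating Hill response H_a(x) = x^n/(K^n + x^n) - gamma x
hill_activation_deriv <- function(x, n, K, gamma = 0) {
  n * K^n * x^(n - 1) / (K^n + x^n)^2 - gamma
}

hill_inhibition_deriv <- function(x, n, K, gamma = 0) {
  -n * K^n * x^(n - 1) / (K^n + x^n)^2 - gamma
}

#' Fit Hill-response derivatives to Jacobian-vs-expression profiles
#'
#' The fitted vector field encodes regulatory response functions only
#' implicitly; assuming a Hill-type interaction, its parameters can be
#' recovered by fitting the derivative of an activating
#' (`n K^n x^(n-1) / (K^n + x^n)^2 - gamma`) or inhibitory (negated first
#' term) Hill function to the per-cell Jacobian entry as a function of the
#' regulator's expression. Cells are pooled into `bins` equal-count
#' expression bins; bin means are fit weighted by inverse bin standard
#' deviation. The degradation rate `gamma` is estimated only for
#' self-interactions and fixed to 0 otherwise.
#'
#' @param expression per-cell regulator expression.
#' @param jacobian_values per-cell Jacobian entries `d f_target / d x_reg`.
#' @param interaction `"activation"`, `"inhibition"` or `"self"` (activating
#'   with free degradation).
#' @param bins number of equal-count bins (default 20).
#' @return object of class `HillFit`: list with `n`, `K`, `gamma`,
#'   `residual`, `converged`.
#' @export
fit_hill <- function(expression, jacobian_values,
                     interaction = c("activation", "inhibition", "self"),
                     bins = 20) {
  interaction <- match.arg(interaction)
  stopifnot(length(expression) == length(jacobian_values),
            length(expression) >= 20)
  qs <- stats::quantile(expression, probs = seq(0, 1, length.out = bins + 1))
  grp <- cut(expression, unique(qs), include.lowest = TRUE)
  xb <- tapply(expression, grp, mean)
  yb <- tapply(jacobian_values, grp, mean)
  sb <- tapply(jacobian_values, grp, stats::sd)
  ok <- is.finite(xb) & is.finite(yb)
  xb <- xb[ok]; yb <- yb[ok]; sb <- sb[ok]
  sb[!is.finite(sb) | sb <= 0] <- stats::median(sb[is.finite(sb) & sb > 0],
                                                na.rm = TRUE)
  if (all(!is.finite(sb))) sb <- rep(1, length(xb))
  wts <- 1 / sb
  form <- if (interaction == "inhibition") hill_inhibition_deriv else
    hill_activation_deriv
  free_gamma <- interaction == "self"
  resid_fun <- function(par) {
    n <- exp(par[1]); K <- exp(par[2])
    gamma <- if (free_gamma) par[3] else 0
    wts * (yb - form(xb, n, K, gamma))
  }
  start <- c(log(2), log(stats::median(expression)))
  if (free_gamma) start <- c(start, 0)
  fit <- tryCatch(
    minpack.lm::nls.lm(par = start, fn = resid_fun,
                       control = minpack.lm::nls.lm.control(maxiter = 500)),
    error = function(e) NULL)
  if (is.null(fit))
    return(structure(list(n = NA_real_, K = NA_real_, gamma = NA_real_,
                          residual = NA_real_, converged = FALSE),
                     class = "HillFit"))
  structure(list(n = exp(fit$par[1]), K = exp(fit$par[2]),
                 gamma = if (free_gamma) fit$par[3] else 0,
                 residual = sum(fit$fvec^2), converged = TRUE),
            class = "HillFit")
}
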