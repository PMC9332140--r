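#' @useDynLib dynofield, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# ---- helpers -------------------------------------------------------------

# cells in the top quantile of a per-gene expression score ("extreme" cells
# near steady state in the phase plane). Top 5% with a floor of 10 cells.
extreme_cells <- function(score, q = 0.05, min_cells = 10) {
  n <- length(score)
  n_ext <- min(n, max(ceiling(q * n), min_cells))
  order(score, decreasing = TRUE)[seq_len(n_ext)]
}

# R-squared as used for the linear-regression goodness of fit
r_squared <- function(data, pred) {
  ss_res <- sum((data - pred)^2)
  ss_tot <- sum((data - mean(data))^2)
  if (ss_tot == 0) return(if (ss_res == 0) 1 else 0)
  1 - ss_res / ss_tot
}

# Gaussian log-likelihood goodness of fit for curve fits: each species is
# normalized by the maximum of its data before comparing data x to model
# predictions y.
gaussian_loglik <- function(data_list, pred_list) {
  stopifnot(length(data_list) == length(pred_list))
  ll <- 0
  n_tot <- 0
  for (i in seq_along(data_list)) {
    x <- data_list[[i]]; y <- pred_list[[i]]
    mx <- max(abs(x))
    if (mx > 0) { x <- x / mx; y <- y / mx }
    s <- stats::sd(x)
    if (!is.finite(s) || s <= 0) s <- 1e-8
    ll <- ll - log(s) - 0.5 * sum((x - y)^2)
    n_tot <- n_tot + length(x)
  }
  ll - n_tot / 2 * log(2 * pi)
}

new_kinetic_estimate <- function(genes, method) {
  structure(list(
    genes = data.frame(gene = genes,
                       gamma_tilde = NA_real_, gamma = NA_real_,
                       beta = NA_real_, alpha = NA_real_, k = NA_real_,
                       half_life = NA_real_, r2 = NA_real_,
                       loglik = NA_real_, unfit = FALSE,
                       stringsAsFactors = FALSE),
    alpha_cell = NULL,      # cells x genes matrix when cell-wise alpha exists
    velocity = list(),      # named list of cells x genes velocity matrices
    method = method),
    class = "KineticEstimate")
}

#' @exportS3Method print KineticEstimate
print.KineticEstimate <- function(x, ...) {
  g <- x$genes
  cat(sprintf("KineticEstimate (%s): %d genes, %d fit\n",
              x$method, nrow(g), sum(!g$unfit)))
  if (length(x$velocity))
    cat("  velocity layers:", paste(names(x$velocity), collapse = ", "), "\n")
  invisible(x)
}

#' @exportS3Method summary KineticEstimate
summary.KineticEstimate <- function(object, ...) {
  g <- object$genes[!object$genes$unfit, , drop = FALSE]
  cat(sprintf("KineticEstimate (%s)\n", object$method))
  for (col in c("gamma_tilde", "gamma", "beta", "k", "half_life", "r2")) {
    v <- g[[col]]
    if (all(is.na(v))) next
    cat(sprintf("  %-12s median %.4g  [%.4g, %.4g]\n", col,
                stats::median(v, na.rm = TRUE), min(v, na.rm = TRUE),
                max(v, na.rm = TRUE)))
  }
  invisible(object)
}

#' @exportS3Method coef KineticEstimate
coef.KineticEstimate <- function(object, ...) {
  object$genes
}

# ---- conventional (splicing) estimators ----------------------------------

#' Steady-state relative degradation rate from splicing data
#'
#' Under the pseudo-steady-state assumption `beta*u = gamma*s` for cells
#' with extreme high expression, a zero-intercept least-squares fit of
#' `u = gamma_tilde * s` on those cells yields the dimensionless relative
#' degradation rate `gamma_tilde = gamma / beta` per gene, and the
#' conventional (relative) RNA velocity `v = u - gamma_tilde * s`.
#'
#' @param ms a [smooth_moments()] result with `u`/`s` moments.
#' @param extreme_quantile fraction of top-expressing cells used (default
#'   0.05, floor of 10 cells).
#' @return a `KineticEstimate` with `gamma_tilde`, per-gene fit R2 and a
#'   spliced velocity matrix (`velocity$s`, relative units).
#' @export
fit_gamma_tilde_ss <- function(ms, extreme_quantile = 0.05) {
  stopifnot(inherits(ms, "MomentSet"), !is.null(ms$m_u), !is.null(ms$m_s))
  genes <- ms$gene_ids
  est <- new_kinetic_estimate(genes, "steady-state")
  V <- matrix(NA_real_, nrow(ms$m_u), length(genes),
              dimnames = dimnames(ms$m_u))
  for (j in seq_along(genes)) {
    u <- ms$m_u[, j]; s <- ms$m_s[, j]
    sel <- extreme_cells(u + s, extreme_quantile)
    if (sum((u + s)[sel] > 0) < 5) { est$genes$unfit[j] <- TRUE; next }
    denom <- sum(s[sel]^2)
    if (denom == 0) { est$genes$unfit[j] <- TRUE; next }
    gt <- sum(u[sel] * s[sel]) / denom
    est$genes$gamma_tilde[j] <- gt
    est$genes$r2[j] <- r_squared(u[sel], gt * s[sel])
    V[, j] <- u - gt * s
  }
  est$velocity$s <- V
  est
}

#' Generalized method-of-moments relative degradation rate
#'
#' Two estimators that use second moments in addition to means. The
#' `stochastic` variant solves the master-equation moment conditions
#' `y = gamma_tilde * x` with `x = (<s>, 2<s^2> - <s>)` and
#' `y = (<u>, <u> + 2<us>)` by (optionally weighted) least squares over
#' the extreme cells. The `negbin` variant assumes spliced counts are
#' negative-binomial at steady state with reciprocal dispersion
#' `phi = (Var(s) - <s>) / <s>^2` and solves the pair of moment conditions
#' `gamma_tilde <s> = <u>` and
#' `gamma_tilde^2 Var(s) = gamma_tilde <u> - phi <u>^2`
#' by one-dimensional nonlinear least squares; for underdispersed genes
#' (`phi <= 0`) it falls back to the stochastic variant with a warning.
#'
#' @param ms a [smooth_moments()] result.
#' @param variant `"stochastic"` or `"negbin"`.
#' @param W optional 2x2 weighting matrix for the stochastic variant
#'   (identity by default; supply an inverse error covariance to reproduce
#'   the classical GMM weighting).
#' @param extreme_quantile as in [fit_gamma_tilde_ss()].
#' @return a `KineticEstimate`.
#' @export
fit_gamma_tilde_gmm <- function(ms, variant = c("stochastic", "negbin"),
                                W = NULL, extreme_quantile = 0.05) {
  variant <- match.arg(variant)
  stopifnot(inherits(ms, "MomentSet"), !is.null(ms$m_u), !is.null(ms$v_s),
            !is.null(ms$m_us))
  genes <- ms$gene_ids
  est <- new_kinetic_estimate(genes, paste0("gmm-", variant))
  if (is.null(W)) W <- diag(2)
  V <- matrix(NA_real_, nrow(ms$m_u), length(genes),
              dimnames = dimnames(ms$m_u))
  for (j in seq_along(genes)) {
    u <- ms$m_u[, j]; s <- ms$m_s[, j]
    s2 <- ms$v_s[, j]; us <- ms$m_us[, j]
    sel <- extreme_cells(u + s, extreme_quantile)
    if (sum((u + s)[sel] > 0) < 5) { est$genes$unfit[j] <- TRUE; next }
    gt_sto <- gmm_stochastic_slope(u[sel], s[sel], s2[sel], us[sel], W)
    gt <- gt_sto
    if (variant == "negbin") {
      # cell-wise central variance of s and reciprocal dispersion
      vs_i <- s2[sel] - s[sel]^2
      ok_i <- s[sel] > 0
      phi_hat <- mean(((vs_i - s[sel]) / s[sel]^2)[ok_i])
      if (!is.finite(phi_hat) || phi_hat <= 0) {
        warning("gene ", genes[j],
                ": underdispersed (phi <= 0), falling back to stochastic")
      } else {
        ui <- u[sel]; si <- s[sel]
        obj <- function(g) {
          sum((g * si - ui)^2 +
              (g^2 * vs_i - g * ui + phi_hat * ui^2)^2)
        }
        opt <- stats::optimize(obj, c(1e-8, max(10 * gt_sto, 10)))
        gt <- opt$minimum
      }
    }
    if (!is.finite(gt)) { est$genes$unfit[j] <- TRUE; next }
    est$genes$gamma_tilde[j] <- gt
    est$genes$r2[j] <- r_squared(u[sel], gt * s[sel])
    V[, j] <- u - gt * s
  }
  est$velocity$s <- V
  est
}

gmm_stochastic_slope <- function(u, s, s2, us, W) {
  num <- 0; den <- 0
  for (i in seq_along(u)) {
    x <- c(s[i], 2 * s2[i] - s[i])
    y <- c(u[i], u[i] + 2 * us[i])
    num <- num + drop(crossprod(x, W %*% y))
    den <- den + drop(crossprod(x, W %*% x))
  }
  if (den == 0) return(NA_real_)
  num / den
}

# ---- labeling-based estimators -------------------------------------------

#' One-shot labeling estimator of absolute degradation rate and velocity
#'
#' With a single labeling window of duration `t`, labeled and total RNA of a
#' gene at steady state satisfy `l = k r` with slope
#' `k = rho (1 - exp(-gamma t))`. The slope is estimated by zero-intercept
#' regression on extreme cells (or by negative-binomial moment conditions on
#' `l`, `r`), and with well-corrected labeling (`rho ~ 1`) the absolute
#' degradation rate follows as `gamma = -log(1 - k) / t` (1/h). The total
#' RNA velocity per cell is `r_dot = (gamma / k) l - gamma r` and the
#' cell-wise transcription rate is `alpha = gamma l / (1 - exp(-gamma t))`.
#'
#' @param lm a [layered_matrix()] with `l` and `r` layers (one_shot design),
#'   or a [smooth_moments()] result via `ms`.
#' @param ms optional `MomentSet`; when supplied, smoothed moments are used
#'   instead of raw counts.
#' @param use_negbin use the negative-binomial moment conditions for the
#'   slope instead of least squares.
#' @param extreme_quantile as in [fit_gamma_tilde_ss()].
#' @param t labeling duration in hours; defaults to the container's.
#' @return a `KineticEstimate` with `gamma`, `k`, `half_life`, per-cell
#'   `alpha` and total-RNA velocity (`velocity$r`, molecules/h).
#' @export
fit_one_shot <- function(lm, ms = NULL, use_negbin = FALSE,
                         extreme_quantile = 0.05, t = NULL) {
  stopifnot(inherits(lm, "LayeredMatrix"),
            all(c("l", "r") %in% names(lm$layers)))
  if (is.null(t)) t <- unique(lm$label_time)[1]
  stopifnot(is.finite(t), t > 0)
  L <- if (!is.null(ms)) ms$m_l else lm$layers$l
  R <- if (!is.null(ms)) ms$m_r else lm$layers$r
  genes <- lm$gene_ids
  est <- new_kinetic_estimate(genes, if (use_negbin) "one-shot-nb" else "one-shot")
  V <- matrix(NA_real_, nrow(L), length(genes), dimnames = dimnames(L))
  A <- matrix(NA_real_, nrow(L), length(genes), dimnames = dimnames(L))
  for (j in seq_along(genes)) {
    fit <- one_shot_slope(L[, j], R[, j], use_negbin, extreme_quantile)
    if (is.na(fit$k) || fit$k <= 0 || fit$k >= 1) {
      est$genes$unfit[j] <- TRUE
      next
    }
    k <- fit$k
    gamma <- -log(1 - k) / t
    est$genes$k[j] <- k
    est$genes$gamma[j] <- gamma
    est$genes$half_life[j] <- log(2) / gamma
    est$genes$r2[j] <- fit$r2
    V[, j] <- (gamma / k) * L[, j] - gamma * R[, j]
    A[, j] <- gamma * L[, j] / (1 - exp(-gamma * t))
  }
  est$velocity$r <- V
  est$alpha_cell <- A
  est$genes$alpha <- colMeans(A)
  est
}

one_shot_slope <- function(l, r, use_negbin, extreme_quantile) {
  # extremes are scored on the regressor r alone: conditional on r the
  # labeled count has mean k*r, so selecting on r leaves the zero-intercept
  # slope unbiased, whereas selecting on l + r co-selects the labeled noise
  sel <- extreme_cells(r, extreme_quantile)
  if (sum((l + r)[sel] > 0) < 5) return(list(k = NA_real_, r2 = NA_real_))
  denom <- sum(r[sel]^2)
  if (denom == 0) return(list(k = NA_real_, r2 = NA_real_))
  k_ls <- sum(l[sel] * r[sel]) / denom
  k <- k_ls
  if (use_negbin) {
    mr <- mean(r[sel]); ml <- mean(l[sel])
    vr <- mean(r[sel]^2) - mr^2
    phi_hat <- if (mr > 0) (vr - mr) / mr^2 else NA_real_
    if (is.finite(phi_hat) && phi_hat > 0) {
      obj <- function(k) {
        (k * mr - ml)^2 + (k^2 * vr - k * ml + phi_hat * ml^2)^2
      }
      k <- stats::optimize(obj, c(1e-8, 1 - 1e-8))$minimum
    }
  }
  list(k = k, r2 = r_squared(l[sel], k * r[sel]))
}

#' Two-step estimator for kinetics (pulse) experiments
#'
#' Step 1 fits the labeled-vs-total slope `k(t)` separately for every
#' labeling duration (exactly the one-shot slope). Since
#' `k(t) = 1 - exp(-gamma t)`, step 2 regresses `-log(1 - k)` on `t`
#' through the origin to obtain the absolute degradation rate `gamma`.
#' The step-2 R-squared measures how consistently the gene follows
#' first-order kinetics and is used for gene filtering. With a single time
#' point the estimator reduces exactly to [fit_one_shot()].
#'
#' @inheritParams fit_one_shot
#' @return a `KineticEstimate`; `velocity$r` uses the per-cell slope
#'   `k(t_cell)` of each cell's own labeling duration.
#' @export
fit_two_step <- function(lm, ms = NULL, use_negbin = FALSE,
                         extreme_quantile = 0.05) {
  stopifnot(inherits(lm, "LayeredMatrix"),
            all(c("l", "r") %in% names(lm$layers)),
            !is.null(lm$label_time))
  L <- if (!is.null(ms)) ms$m_l else lm$layers$l
  R <- if (!is.null(ms)) ms$m_r else lm$layers$r
  tt <- lm$label_time
  times <- sort(unique(tt))
  genes <- lm$gene_ids
  est <- new_kinetic_estimate(genes, "two-step")
  V <- matrix(NA_real_, nrow(L), length(genes), dimnames = dimnames(L))
  A <- matrix(NA_real_, nrow(L), length(genes), dimnames = dimnames(L))
  for (j in seq_along(genes)) {
    ks <- vapply(times, function(ti) {
      idx <- which(tt == ti)
      one_shot_slope(L[idx, j], R[idx, j], use_negbin, extreme_quantile)$k
    }, numeric(1))
    ok <- is.finite(ks) & ks > 0 & ks < 1
    if (sum(ok) < 1 || (length(times) > 1 && sum(ok) < 2)) {
      est$genes$unfit[j] <- TRUE
      next
    }
    tv <- times[ok]
    yv <- -log(1 - ks[ok])
    gamma <- sum(tv * yv) / sum(tv^2)   # zero-intercept regression on t
    if (!is.finite(gamma) || gamma <= 0) { est$genes$unfit[j] <- TRUE; next }
    est$genes$gamma[j] <- gamma
    est$genes$half_life[j] <- log(2) / gamma
    est$genes$r2[j] <- r_squared(yv, gamma * tv)
    est$genes$k[j] <- ks[match(max(tv), times)]
    k_cell <- stats::setNames(ks, as.character(times))[as.character(tt)]
    V[, j] <- (gamma / k_cell) * L[, j] - gamma * R[, j]
    A[, j] <- gamma * L[, j] / (1 - exp(-gamma * tt))
  }
  est$velocity$r <- V
  est$alpha_cell <- A
  est$genes$alpha <- colMeans(A)
  est
}

# ---- curve-fitting estimators --------------------------------------------

# closed-form solutions of the labeling/splicing ODEs.
# Model 2 (no splicing): labeled l' = rho*alpha - gamma*l, total r' = alpha - gamma*r.
# Model 3 (with splicing): unspliced-labeled and spliced-labeled species.
model2_kinetics_sol <- function(t, alpha, gamma, rho = 1) {
  rho * alpha / gamma * (1 - exp(-gamma * t))
}

model2_degradation_sol <- function(t, l0, gamma) {
  l0 * exp(-gamma * t)
}

# general Model 3 solution with initial conditions; the beta == gamma branch
# follows the degenerate closed form (taken when |beta - gamma|/gamma < 1e-3)
model3_sol <- function(t, alpha, beta, gamma, u0 = 0, s0 = 0, rho = 1) {
  u <- u0 * exp(-beta * t) + rho * alpha / beta * (1 - exp(-beta * t))
  if (abs(beta - gamma) / gamma < 1e-3) {
    s <- s0 * exp(-gamma * t) + rho * alpha / gamma * (1 - exp(-gamma * t)) +
      (beta * u0 - rho * alpha) * t * exp(-gamma * t)
  } else {
    s <- s0 * exp(-gamma * t) + rho * alpha / gamma * (1 - exp(-gamma * t)) +
      (rho * alpha - u0 * beta) / (gamma - beta) *
        (exp(-gamma * t) - exp(-beta * t))
  }
  list(u = u, s = s)
}

# unlabeled species during a kinetics experiment decay from their initial
# steady-state abundances
model3_unlabeled_sol <- function(t, beta, gamma, uu0, su0) {
  u <- uu0 * exp(-beta * t)
  if (abs(beta - gamma) / gamma < 1e-3) {
    s <- su0 * exp(-gamma * t) - beta * uu0 * t * exp(-gamma * t)
  } else {
    s <- su0 * exp(-gamma * t) -
      beta * uu0 / (gamma - beta) * (exp(-gamma * t) - exp(-beta * t))
  }
  list(u = u, s = s)
}

#' Guesstimated parameter values and ranges for curve fitting
#'
#' Order-of-magnitude starting values derived directly from the data, used
#' to seed and bound the nonlinear least-squares fits. For kinetics
#' experiments `alpha0 = mean(l / t)`, `gamma0 = log(o_first / o_last) / dt`
#' from old RNA and `beta0` likewise from unlabeled-unspliced RNA; for
#' degradation experiments `gamma0 = log(l_first / l_last) / dt`
#' (sign-corrected to positive) and `beta0` from labeled-unspliced RNA.
#' The search range for each parameter is `(0, 100 * theta0)`.
#'
#' @param lm a [layered_matrix()] (kinetics or degradation design).
#' @param gene gene index or id.
#' @return list with `theta0`, `lower`, `upper` (named vectors) and
#'   `fallback` flag set when a guess had to default to 1.
#' @export
guesstimate_ranges <- function(lm, gene) {
  stopifnot(inherits(lm, "LayeredMatrix"))
  j <- if (is.character(gene)) match(gene, lm$gene_ids) else gene
  tt <- lm$label_time
  times <- sort(unique(tt))
  fallback <- FALSE
  guess_rate <- function(x_first, x_last, dt) {
    if (is.finite(x_first) && is.finite(x_last) &&
        x_first > 0 && x_last > 0 && dt > 0 && x_first != x_last) {
      abs(log(x_first / x_last)) / dt
    } else {
      fallback <<- TRUE
      1
    }
  }
  mean_at <- function(M, ti) mean(M[tt == ti, j])
  dt <- max(times) - min(times)
  if (lm$experiment_type == "kinetics") {
    l <- lm$layers$l[, j]
    alpha0 <- mean((l / tt)[tt > 0])
    if (!is.finite(alpha0) || alpha0 <= 0) { alpha0 <- 1; fallback <- TRUE }
    if (all(c("l", "r") %in% names(lm$layers))) {
      o <- get_layer(lm, "o")[, j]
      o_first <- mean(o[tt == min(times)]); o_last <- mean(o[tt == max(times)])
      gamma0 <- guess_rate(o_first, o_last, dt)
    } else { gamma0 <- 1; fallback <- TRUE }
    beta0 <- if ("u" %in% names(lm$layers)) {
      guess_rate(mean_at(lm$layers$u, min(times)),
                 mean_at(lm$layers$u, max(times)), dt)
    } else gamma0 * 2
    theta0 <- c(alpha = alpha0, beta = beta0, gamma = gamma0)
  } else if (lm$experiment_type == "degradation") {
    l_first <- mean_at(lm$layers$l, min(times))
    l_last <- mean_at(lm$layers$l, max(times))
    gamma0 <- guess_rate(l_first, l_last, dt)
    beta0 <- if ("u" %in% names(lm$layers)) {
      guess_rate(mean_at(lm$layers$u, min(times)),
                 mean_at(lm$layers$u, max(times)), dt)
    } else gamma0 * 2
    theta0 <- c(beta = beta0, gamma = gamma0)
  } else {
    stop("guesstimation is defined for kinetics and degradation designs")
  }
  list(theta0 = theta0,
       lower = stats::setNames(rep(0, length(theta0)), names(theta0)),
       upper = 100 * theta0, fallback = fallback)
}

#' Nonlinear least-squares curve fit of labeling kinetics
#'
#' Fits the closed-form solutions of the labeling ODEs to per-cell species
#' abundances across labeling time points, minimizing the weighted squared
#' loss `L(theta) = sum_j w_j sum_i (y_j^(i) - x_j(t^(i), theta))^2` over
#' all species j and cells i. Kinetics (pulse) designs fit the rise of
#' labeled species (and optionally the decay of unlabeled species);
#' degradation (chase) designs fit first-order decay. Optimization is
#' multi-start Levenberg-Marquardt from Latin-hypercube draws over
#' guesstimated parameter ranges.
#'
#' @param lm a [layered_matrix()] with a `kinetics` or `degradation` design.
#' @param model `"model2"` (no splicing; species `l`, optionally `o`) or
#'   `"model3"` (splicing; species `u`/`s` interpreted as labeled unspliced
#'   and spliced, optionally unlabeled counterparts via `r`-derived layers).
#' @param weights named per-species weights; defaults to 2 for labeled and
#'   1 for unlabeled species.
#' @param rho labeling correction coefficient (default 1).
#' @param n_starts Latin-hypercube multi-start count (default 20).
#' @param by_group fit a separate transcription rate per `lm$group` level.
#' @param seed RNG seed for the Latin-hypercube draws.
#' @return a `KineticEstimate` with absolute rates, per-gene Gaussian
#'   log-likelihood and spliced/total velocities where defined.
#' @export
fit_curve <- function(lm, model = c("model2", "model3"), weights = NULL,
                      rho = 1, n_starts = 20, by_group = FALSE, seed = 0) {
  model <- match.arg(model)
  stopifnot(inherits(lm, "LayeredMatrix"),
            lm$experiment_type %in% c("kinetics", "degradation"))
  genes <- lm$gene_ids
  est <- new_kinetic_estimate(genes, paste0("curve-", model))
  tt <- lm$label_time
  groups <- if (by_group && !is.null(lm$group)) lm$group else
    factor(rep("all", length(tt)))
  alpha_cluster <- matrix(NA_real_, nlevels(groups), length(genes),
                          dimnames = list(levels(groups), genes))
  for (j in seq_along(genes)) {
    fit <- tryCatch(
      fit_curve_gene(lm, j, model, weights, rho, n_starts, groups, seed),
      error = function(e) NULL)
    if (is.null(fit)) { est$genes$unfit[j] <- TRUE; next }
    for (nm in intersect(names(fit$theta), c("alpha", "beta", "gamma")))
      est$genes[[nm]][j] <- fit$theta[[nm]]
    if (!is.null(fit$theta[["gamma"]]))
      est$genes$half_life[j] <- log(2) / fit$theta[["gamma"]]
    est$genes$loglik[j] <- fit$loglik
    est$genes$r2[j] <- fit$r2
    if (!is.null(fit$alpha_by_group))
      alpha_cluster[, j] <- fit$alpha_by_group
  }
  if (by_group) est$alpha_cluster <- alpha_cluster
  # velocities from fitted rates
  if (model == "model3" && all(c("u", "s") %in% names(lm$layers))) {
    beta <- est$genes$beta; gamma <- est$genes$gamma
    est$velocity$s <- sweep(lm$layers$u, 2, beta, "*") -
      sweep(lm$layers$s, 2, gamma, "*")
  }
  if (model == "model2" && all(c("l", "r") %in% names(lm$layers)) &&
      lm$experiment_type == "kinetics") {
    gamma <- est$genes$gamma
    kmat <- outer(tt, gamma, function(t, g) 1 - exp(-g * t))
    est$velocity$r <- lm$layers$l * sweep(1 / kmat, 2, gamma, "*") -
      sweep(lm$layers$r, 2, gamma, "*")
  }
  est
}

fit_curve_gene <- function(lm, j, model, weights, rho, n_starts, groups,
                           seed) {
  tt <- lm$label_time
  design <- lm$experiment_type
  gg <- guesstimate_ranges(lm, j)
  # assemble species data and predictors
  if (model == "model2") {
    species <- list(l = lm$layers$l[, j])
    w <- c(l = 2)
    if (design == "kinetics" && all(c("l", "r") %in% names(lm$layers))) {
      species$o <- get_layer(lm, "o")[, j]
      w["o"] <- 1
    }
    if (design == "kinetics") {
      par_names <- c("alpha", "gamma")
      predict_fun <- function(th, t) {
        list(l = model2_kinetics_sol(t, th[["alpha"]], th[["gamma"]], rho),
             o = if ("o" %in% names(species)) {
               o0 <- mean(species$o[tt == min(tt)])
               o0 * exp(-th[["gamma"]] * t)
             })
      }
      theta0 <- gg$theta0[c("alpha", "gamma")]
    } else {
      l0 <- mean(species$l[tt == min(tt)])
      par_names <- c("gamma")
      predict_fun <- function(th, t) {
        list(l = model2_degradation_sol(t - min(tt), l0, th[["gamma"]]))
      }
      theta0 <- gg$theta0["gamma"]
    }
  } else { # model3: u and s layers hold the labeled unspliced/spliced species
    stopifnot(all(c("u", "s") %in% names(lm$layers)))
    species <- list(u = lm$layers$u[, j], s = lm$layers$s[, j])
    w <- c(u = 2, s = 2)
    if (design == "kinetics") {
      par_names <- c("alpha", "beta", "gamma")
      predict_fun <- function(th, t) {
        sol <- model3_sol(t, th[["alpha"]], th[["beta"]], th[["gamma"]],
                          u0 = 0, s0 = 0, rho = rho)
        list(u = sol$u, s = sol$s)
      }
      theta0 <- gg$theta0[c("alpha", "beta", "gamma")]
    } else {
      u0 <- mean(species$u[tt == min(tt)])
      s0 <- mean(species$s[tt == min(tt)])
      par_names <- c("beta", "gamma")
      predict_fun <- function(th, t) {
        sol <- model3_sol(t - min(tt), 0, th[["beta"]], th[["gamma"]],
                          u0 = u0, s0 = s0, rho = rho)
        list(u = sol$u, s = sol$s)
      }
      theta0 <- gg$theta0[c("beta", "gamma")]
    }
  }
  if (!is.null(weights)) w[names(weights)] <- weights
  lower <- rep(1e-10, length(theta0))
  upper <- 100 * theta0
  residual_fun <- function(log_th) {
    th <- stats::setNames(exp(log_th), par_names)
    pred <- predict_fun(th, tt)
    res <- c()
    for (nm in names(species)) {
      if (is.null(pred[[nm]])) next
      res <- c(res, sqrt(w[[nm]]) * (species[[nm]] - pred[[nm]]))
    }
    res
  }
  # multi-start: theta0 itself plus LHS draws log-uniform in
  # [theta0/100, 100*theta0]
  set.seed(seed + j)
  draws <- lhs::randomLHS(n_starts - 1, length(theta0))
  starts <- rbind(log(theta0),
                  sweep(sweep(draws, 2, log(1e4), "*"), 2,
                        log(theta0 / 100), "+"))
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    fit <- tryCatch(
      minpack.lm::nls.lm(par = starts[i, ], fn = residual_fun,
                         lower = log(pmax(lower, 1e-12)),
                         upper = log(upper),
                         control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit)) next
    loss <- sum(fit$fvec^2)
    if (is.null(best) || loss < best$loss - 1e-12 ||
        (abs(loss - best$loss) <= 1e-12 &&
         sum(exp(fit$par)^2) < sum(exp(best$par)^2))) {
      best <- list(par = fit$par, loss = loss)
    }
  }
  if (is.null(best)) stop("no start converged")
  theta <- stats::setNames(exp(best$par), par_names)
  pred <- predict_fun(theta, tt)
  used <- names(species)[!vapply(pred[names(species)], is.null, logical(1))]
  loglik <- gaussian_loglik(species[used], pred[used])
  r2 <- r_squared(unlist(species[used]), unlist(pred[used]))
  alpha_by_group <- NULL
  if (nlevels(groups) > 1 && "alpha" %in% par_names) {
    alpha_by_group <- vapply(levels(groups), function(gl) {
      idx <- groups == gl
      sub_res <- function(log_a) {
        th <- theta; th[["alpha"]] <- exp(log_a)
        pred <- predict_fun(th, tt[idx])
        unlist(lapply(names(species), function(nm)
          if (!is.null(pred[[nm]]))
            sqrt(w[[nm]]) * (species[[nm]][idx] - pred[[nm]])))
      }
      f <- minpack.lm::nls.lm(par = log(theta[["alpha"]]), fn = sub_res)
      exp(f$par)
    }, numeric(1))
  }
  list(theta = theta, loss = best$loss, loglik = loglik, r2 = r2,
       alpha_by_group = alpha_by_group)
}

# ---- combining relative and absolute rates -------------------------------

#' Unify labeling-derived absolute rates with splicing-derived relative rates
#'
#' Labeling experiments give the absolute degradation rate `gamma` (1/h);
#' splicing data give the relative rate `gamma_tilde = gamma / beta`. Their
#' ratio yields the absolute splicing rate `beta = gamma / gamma_tilde`,
#' which converts the relative spliced velocity into absolute units:
#' `s_dot = beta u - gamma s`. Unspliced and new-RNA velocities follow as
#' `u_dot = beta u_l / (1 - exp(-beta t)) - beta u` and
#' `l_dot = gamma l / (1 - exp(-gamma t)) - gamma l`.
#'
#' @param est a labeling-based `KineticEstimate` carrying `gamma`.
#' @param gamma_tilde per-gene relative rates (vector aligned with
#'   `est$genes$gene`, or a `KineticEstimate` from a splicing fit).
#' @param lm optional [layered_matrix()]; when it has the needed layers the
#'   absolute velocity matrices are (re)computed and attached.
#' @return the input estimate with `beta` filled and velocities added.
#' @export
unify_beta <- function(est, gamma_tilde, lm = NULL) {
  stopifnot(inherits(est, "KineticEstimate"))
  if (inherits(gamma_tilde, "KineticEstimate"))
    gamma_tilde <- gamma_tilde$genes$gamma_tilde
  stopifnot(length(gamma_tilde) == nrow(est$genes))
  ok <- is.finite(gamma_tilde) & gamma_tilde > 0 & is.finite(est$genes$gamma)
  est$genes$gamma_tilde <- gamma_tilde
  est$genes$beta[ok] <- est$genes$gamma[ok] / gamma_tilde[ok]
  if (!is.null(lm)) {
    beta <- est$genes$beta; gamma <- est$genes$gamma
    if (all(c("u", "s") %in% names(lm$layers)))
      est$velocity$s <- sweep(lm$layers$u, 2, beta, "*") -
        sweep(lm$layers$s, 2, gamma, "*")
    if ("l" %in% names(lm$layers) && !is.null(lm$label_time)) {
      tt <- lm$label_time
      kmat <- outer(tt, gamma, function(t, g) 1 - exp(-g * t))
      est$velocity$l <- lm$layers$l * sweep(1 / kmat, 2, gamma, "*") -
        sweep(lm$layers$l, 2, gamma, "*")
    }
  }
  est
}

#' Bias in the degradation rate from mis-estimated labeled fractions
#'
#' When the labeled fraction is systematically off by a correction
#' coefficient `rho` (true slope `k rho` mistaken for `k`), the recovered
#' degradation rate is biased by
#' `gamma - gamma_true = -(1/t) log((1 - k rho) / (1 - k))`:
#' under-correction (`rho < 1`) underestimates both `gamma` and the total
#' velocity magnitude, over-correction the reverse.
#'
#' @param rho labeling correction coefficient (`> 0`, `k * rho < 1`).
#' @param k observed labeled/total slope in `(0, 1)`.
#' @param t labeling duration (h).
#' @return list with `delta_gamma` and `velocity_bias_sign` (-1, 0 or 1).
#' @export
labeling_bias <- function(rho, k, t) {
  stopifnot(rho > 0, k > 0, k < 1, t > 0)
  if (k * rho >= 1) stop("k * rho must be < 1")
  dg <- -(1 / t) * log((1 - k * rho) / (1 - k))
  list(delta_gamma = dg, velocity_bias_sign = sign(dg))
}

# ---- transcriptional bursting --------------------------------------------

#' Burst frequency and burst size from negative-binomial moments
#'
#' At steady state of the two-state (telegraph) promoter model in the bursty
#' regime, total RNA counts are negative-binomial with
#' `Var(r) = <r> + phi <r>^2`. The reciprocal dispersion identifies the
#' promoter activation rate (`BF = k_on = gamma / phi`, bursts per hour) and
#' the mean transcripts per burst (`BS = alpha / k_off = <r> phi`).
#'
#' @param mean_r,var_r per-gene mean and variance of total RNA counts
#'   (raw counts, not smoothed moments).
#' @param gamma per-gene absolute degradation rates (1/h).
#' @return object of class `BurstStats`: data.frame with `phi`, `bf`, `bs`
#'   and a `flagged` column for genes at or below the Poisson limit.
#' @export
burst_stats <- function(mean_r, var_r, gamma) {
  stopifnot(length(mean_r) == length(var_r),
            length(gamma) == length(mean_r))
  phi <- (var_r - mean_r) / mean_r^2
  flagged <- !is.finite(phi) | phi <= 0
  phi[flagged] <- NA_real_
  out <- data.frame(phi = phi, bf = gamma / phi, bs = mean_r * phi,
                    flagged = flagged)
  class(out) <- c("BurstStats", "data.frame")
  out
}
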