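#' Exact stochastic simulation of labeled gene expression
#'
#' Gillespie simulation of the two-state (telegraph) promoter model with
#' transcription, optional splicing, first-order degradation and
#' nucleoside-analog labeling: molecules transcribed during the labeling
#' window are labeled with probability `rho`. Each cell is simulated to
#' stationarity (burn-in of `10 / gamma` time units), then through the
#' labeling design:
#' * `one_shot`: a single labeling window of `t_label` hours;
#' * `kinetics`: cells split evenly over the `t_label` durations;
#' * `degradation`: an extended labeling period (`5 / gamma`) followed by a
#'   chase of duration drawn from `t_chase` per cell (label times recorded
#'   as the chase times).
#'
#' @param n_cells cells to simulate per gene.
#' @param n_genes independent replicate genes (same parameters; vectorized
#'   parameters recycle across genes).
#' @param k_on,k_off promoter activation/inactivation rates (1/h); set
#'   `constitutive = TRUE` for an always-active promoter.
#' @param alpha_on,alpha_off transcription rates in the active/inactive
#'   state (molecules/h); `alpha_off` defaults to 0.
#' @param beta splicing rate (1/h); ignored when `splicing = FALSE`.
#' @param gamma degradation rate (1/h).
#' @param rho labeling efficiency in (0, 1].
#' @param splicing simulate unspliced/spliced species.
#' @param design `"one_shot"`, `"kinetics"` or `"degradation"`.
#' @param t_label labeling duration(s) in hours (one value for one_shot,
#'   several for kinetics).
#' @param t_chase chase durations (degradation design).
#' @param constitutive bypass promoter switching.
#' @param burn_in pre-labeling equilibration time (h); default `10 / gamma`,
#'   capped at 1000 h so that slow (or zero) degradation rates stay finite.
#' @param seed RNG seed.
#' @return a [layered_matrix()] with layers `l`, `r` (plus `u`, `s` when
#'   `splicing`), per-cell `label_time` and the matching experiment type.
#' @export
simulate_expression <- function(n_cells = 1000, n_genes = 1,
                                k_on = 1, k_off = 4,
                                alpha_on = 20, alpha_off = 0,
                                beta = 2, gamma = 0.5, rho = 1,
                                splicing = FALSE,
                                design = c("one_shot", "kinetics",
                                           "degradation"),
                                t_label = 2, t_chase = c(0, 1, 2, 4),
                                constitutive = FALSE, burn_in = NULL,
                                seed = 0) {
  design <- match.arg(design)
  set.seed(seed)
  rec <- function(x) rep_len(x, n_genes)
  k_on <- rec(k_on); k_off <- rec(k_off); alpha_on <- rec(alpha_on)
  alpha_off <- rec(alpha_off); beta <- rec(beta); gamma <- rec(gamma)
  if (design == "one_shot") {
    stopifnot(length(t_label) == 1)
    lab <- rep(t_label, n_cells)
    chase <- rep(0, n_cells)
    label_time <- lab
  } else if (design == "kinetics") {
    stopifnot(length(t_label) >= 2)
    lab <- rep_len(sort(rep(t_label, length.out = n_cells)), n_cells)
    chase <- rep(0, n_cells)
    label_time <- lab
  } else {
    stopifnot(length(t_chase) >= 2)
    chase <- rep_len(sort(rep(t_chase, length.out = n_cells)), n_cells)
    label_time <- chase
  }
  UU <- UL <- SU <- SL <- matrix(0, n_cells, n_genes)
  for (j in seq_len(n_genes)) {
    kon_j <- if (constitutive) 1 else k_on[j]
    koff_j <- if (constitutive) 0 else k_off[j]
    lab_j <- if (design == "degradation")
      rep(min(5 / gamma[j], 500), n_cells) else lab
    bi <- if (is.null(burn_in)) min(10 / gamma[j], 1000) else burn_in
    sim <- simulate_cells_cpp(n_cells, kon_j, koff_j, alpha_on[j],
                              alpha_off[j], beta[j], gamma[j], rho,
                              splicing, bi, lab_j, chase)
    UU[, j] <- sim[, 2]; UL[, j] <- sim[, 3]
    SU[, j] <- sim[, 4]; SL[, j] <- sim[, 5]
  }
  layers <- if (splicing) {
    list(u = UU + UL, s = SU + SL, l = UL + SL, r = UU + UL + SU + SL)
  } else {
    list(l = SL, r = SU + SL)
  }
  layered_matrix(layers, label_time = label_time, experiment_type = design)
}

#' The two-gene toggle-switch benchmark field
#'
#' Canonical mutual-inhibition / self-activation motif:
#' `f1 = a1 x1^n / (K1^n + x1^n) + b1 K1^n / (K1^n + x2^n) - x1` and the
#' mirrored `f2`, with unit degradation. Defaults
#' `a = b = K = 1, n = 4` give two stable attractors (one gene high, the
#' other low) separated by a saddle at `(1, 1)`.
#'
#' @param x states: length-2 vector or n x 2 matrix.
#' @param a,b,K length-2 (recycled) self-activation, basal/inhibition and
#'   threshold parameters.
#' @param n Hill coefficient.
#' @return velocity matrix of the same shape as `x`.
#' @export
toggle_field <- function(x, a = c(1, 1), b = c(1, 1), K = c(1, 1), n = 4) {
  a <- rep_len(a, 2); b <- rep_len(b, 2); K <- rep_len(K, 2)
  vec <- is.null(dim(x))
  if (vec) x <- matrix(x, nrow = 1)
  x1 <- x[, 1]; x2 <- x[, 2]
  f1 <- a[1] * x1^n / (K[1]^n + x1^n) + b[1] * K[1]^n / (K[1]^n + x2^n) - x1
  f2 <- a[2] * x2^n / (K[2]^n + x2^n) + b[2] * K[2]^n / (K[2]^n + x1^n) - x2
  out <- cbind(f1, f2)
  colnames(out) <- NULL
  if (vec) out[1, , drop = TRUE] else out
}

#' Analytic Jacobian of the toggle-switch field
#'
#' `df1/dx1 = a1 n K1^n x1^(n-1) / (K1^n + x1^n)^2 - 1`,
#' `df1/dx2 = -b1 n K1^n x2^(n-1) / (K1^n + x2^n)^2`, mirrored for f2.
#'
#' @inheritParams toggle_field
#' @param x a single length-2 state.
#' @return 2 x 2 Jacobian matrix.
#' @export
toggle_jacobian <- function(x, a = c(1, 1), b = c(1, 1), K = c(1, 1), n = 4) {
  a <- rep_len(a, 2); b <- rep_len(b, 2); K <- rep_len(K, 2)
  x1 <- x[1]; x2 <- x[2]
  j11 <- a[1] * n * K[1]^n * x1^(n - 1) / (K[1]^n + x1^n)^2 - 1
  j12 <- -b[1] * n * K[1]^n * x2^(n - 1) / (K[1]^n + x2^n)^2
  j21 <- -b[2] * n * K[2]^n * x1^(n - 1) / (K[2]^n + x1^n)^2
  j22 <- a[2] * n * K[2]^n * x2^(n - 1) / (K[2]^n + x2^n)^2 - 1
  matrix(c(j11, j21, j12, j22), 2, 2)
}

#' The toggle switch as a `FunctionField`
#'
#' @inheritParams toggle_field
#' @return an [as_vectorfield()] object with analytic Jacobian.
#' @export
toggle_vectorfield <- function(a = c(1, 1), b = c(1, 1), K = c(1, 1), n = 4) {
  as_vectorfield(function(X) toggle_field(X, a, b, K, n),
                 jacobian = function(x) toggle_jacobian(x, a, b, K, n),
                 d = 2)
}

#' Sample (state, velocity) pairs from the toggle-switch field
#'
#' States are drawn uniformly over a rectangular domain (default
#' `[0, 2.5]^2`, the benchmark's expression range); velocities are the
#' exact field values, optionally corrupted with isotropic Gaussian noise
#' whose standard deviation is `noise_sd` times the mean speed.
#'
#' @param n_samples number of points (benchmark default 5000).
#' @param domain 2 x 2 matrix of lower/upper bounds (rows).
#' @param noise_sd velocity noise as a fraction of mean speed (0 = exact).
#' @param seed RNG seed (bit-reproducible output).
#' @inheritParams toggle_field
#' @return list of class `VelocitySamples` with `X`, `V`, `V_true`, `space`.
#' @export
sample_toggle_field <- function(n_samples = 5000,
                                domain = rbind(c(0, 0), c(2.5, 2.5)),
                                noise_sd = 0, seed = 0,
                                a = c(1, 1), b = c(1, 1), K = c(1, 1),
                                n = 4) {
  set.seed(seed)
  X <- cbind(stats::runif(n_samples, domain[1, 1], domain[2, 1]),
             stats::runif(n_samples, domain[1, 2], domain[2, 2]))
  V_true <- toggle_field(X, a, b, K, n)
  V <- V_true
  if (noise_sd > 0) {
    mean_speed <- mean(sqrt(rowSums(V_true^2)))
    V <- V + matrix(stats::rnorm(2 * n_samples, 0, noise_sd * mean_speed),
                    n_samples, 2)
  }
  structure(list(X = X, V = V, V_true = V_true, space = "gene"),
            class = "VelocitySamples")
}
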