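test_that("smoothed moments average the neighborhood including self", {
  # two cells that are each other's neighbor: u = {2, 4}, s = {1, 3}
  lm <- layered_matrix(list(u = matrix(c(2, 4), 2, 1),
                            s = matrix(c(1, 3), 2, 1)))
  g <- structure(list(indices = matrix(c(2L, 1L), 2, 1),
                      distances = matrix(1, 2, 1), K = 1L),
                 class = "NeighborGraph")
  ms <- smooth_moments(lm, g)
  expect_equal(unname(ms$m_u[, 1]), c(3, 3))
  expect_equal(unname(ms$m_us[, 1]), c(7, 7))  # (2*1 + 4*3) / 2
  expect_equal(unname(ms$v_u[, 1]), c(10, 10)) # (4 + 16) / 2
  # constant gene: moments are powers of the constant
  lmc <- layered_matrix(list(u = matrix(5, 2, 1), s = matrix(5, 2, 1)))
  msc <- smooth_moments(lmc, g)
  expect_equal(unname(msc$m_u[, 1]), c(5, 5))
  expect_equal(unname(msc$v_u[, 1]), c(25, 25))
  # identical cells: moments equal raw values
  expect_equal(msc$m_s, lmc$layers$s)
})

test_that("steady-state gamma_tilde matches the zero-intercept closed form", {
  # u = (1,2), s = (2,4) replicated so the extreme-cell floor is met
  u <- rep(c(1, 2), 10); s <- rep(c(2, 4), 10)
  ms <- make_momentset(u, s)
  est <- fit_gamma_tilde_ss(ms, extreme_quantile = 1)
  expect_equal(est$genes$gamma_tilde, 0.5)     # sum(us)/sum(s^2) = 10/20
  expect_equal(est$genes$r2, 1)                # exact linear data
  expect_equal(unname(est$velocity$s[, 1]), u - 0.5 * s)
  # exact data u = 0.5 s: all velocities 0
  expect_true(all(abs(est$velocity$s) < 1e-12))
  # all-zero gene: unfit flag, no NaN leakage
  ms0 <- make_momentset(rep(0, 20), rep(0, 20))
  est0 <- fit_gamma_tilde_ss(ms0)
  expect_true(est0$genes$unfit)
  expect_true(is.na(est0$genes$gamma_tilde))
})

test_that("GMM stochastic slope reproduces the hand-computed weighted LS", {
  # pseudo-cells with <s>=2, <s2>=5, <u>=1, <us>=2:
  # x = (2, 8), y = (1, 5) => gamma_tilde = 42/68
  ms <- make_momentset(rep(1, 10), rep(2, 10), v_s = rep(5, 10),
                       m_us = rep(2, 10))
  est <- fit_gamma_tilde_gmm(ms, "stochastic", extreme_quantile = 1)
  expect_equal(est$genes$gamma_tilde, 42 / 68, tolerance = 1e-12)
})

test_that("negbin variant agrees with stochastic on Poisson-like data and
           falls back when underdispersed", {
  # deterministic u = 0.4 s with Var(s) = <s> (Poisson): phi_hat = 0 exactly
  s <- seq(4, 40, length.out = 30)
  u <- 0.4 * s
  v_s <- s^2 + s                                  # <s^2> = Var + <s>^2
  ms <- make_momentset(u, s, v_s = v_s, m_us = u * s)
  expect_warning(est_nb <- fit_gamma_tilde_gmm(ms, "negbin",
                                               extreme_quantile = 1),
                 "underdispersed")
  est_st <- fit_gamma_tilde_gmm(ms, "stochastic", extreme_quantile = 1)
  expect_equal(est_nb$genes$gamma_tilde, est_st$genes$gamma_tilde,
               tolerance = 1e-6)
})

test_that("one-shot slope, rate and velocity follow the closed forms", {
  lm <- one_shot_fixture(k = 0.5, t = 1)
  est <- fit_one_shot(lm)
  expect_equal(est$genes$k, 0.5, tolerance = 1e-12)
  expect_equal(est$genes$gamma, log(2), tolerance = 1e-12)
  expect_equal(est$genes$half_life, 1, tolerance = 1e-12)
  # steady-state cells on the fit line have zero total velocity
  expect_true(all(abs(est$velocity$r) < 1e-9))
  # k outside (0,1) flags the gene unfit
  lm_bad <- layered_matrix(list(l = matrix(10, 20, 1),
                                r = matrix(10, 20, 1)),
                           label_time = 1, experiment_type = "one_shot")
  expect_true(fit_one_shot(lm_bad)$genes$unfit)
})

test_that("two-step regression recovers gamma from per-time slopes and
           degenerates to one-shot with a single time point", {
  # k(1h) = 0.5, k(2h) = 0.75 => -log(1-k) = (log2, 2 log2) => slope log2
  r <- seq(10, 100, length.out = 30)
  lm <- layered_matrix(
    list(l = matrix(c(0.5 * r, 0.75 * r), ncol = 1),
         r = matrix(c(r, r), ncol = 1)),
    label_time = rep(c(1, 2), each = 30), experiment_type = "kinetics")
  est <- fit_two_step(lm)
  expect_equal(est$genes$gamma, log(2), tolerance = 1e-10)
  expect_equal(est$genes$r2, 1, tolerance = 1e-10)
  # constant k across t: kinetically inconsistent, R^2 collapses to 0
  lm_flat <- layered_matrix(
    list(l = matrix(rep(0.5 * r, 2), ncol = 1),
         r = matrix(rep(r, 2), ncol = 1)),
    label_time = rep(c(1, 2), each = 30), experiment_type = "kinetics")
  expect_lt(fit_two_step(lm_flat)$genes$r2, 0.01)
  # single time point == one-shot exactly
  lm1 <- one_shot_fixture(k = 0.4, t = 2)
  est1 <- fit_one_shot(lm1)
  lm1$experiment_type <- "kinetics"              # bypass the design check
  est2 <- fit_two_step(lm1)
  expect_equal(est2$genes$gamma, est1$genes$gamma, tolerance = 1e-12)
  expect_equal(est2$velocity$r, est1$velocity$r, tolerance = 1e-12)
})

test_that("curve fitting recovers rates from noiseless closed-form fixtures", {
  # degradation: l(t) = 100 exp(-0.5 t) at t = 0, 1, 2, 4
  tt <- rep(c(0, 1, 2, 4), each = 10)
  l <- 100 * exp(-0.5 * tt)
  lm <- layered_matrix(list(l = matrix(l, ncol = 1),
                            r = matrix(l + 50, ncol = 1)),
                       label_time = tt, experiment_type = "degradation")
  expect_equal(l[tt == 0][1], 100)               # t = 0 equals l0 exactly
  est <- fit_curve(lm, model = "model2", n_starts = 5)
  expect_equal(est$genes$gamma, 0.5, tolerance = 1e-4)
  # kinetics with splicing: alpha = 10, beta = 2, gamma = 0.5
  tt2 <- rep(c(0.25, 0.5, 1, 2), each = 10)
  ul <- 10 / 2 * (1 - exp(-2 * tt2))
  sl <- 10 / 0.5 * (1 - exp(-0.5 * tt2)) +
    10 / (0.5 - 2) * (exp(-0.5 * tt2) - exp(-2 * tt2))
  lm2 <- layered_matrix(list(u = matrix(ul, ncol = 1),
                             s = matrix(sl, ncol = 1)),
                        label_time = tt2, experiment_type = "kinetics")
  est2 <- fit_curve(lm2, model = "model3", n_starts = 10)
  expect_equal(est2$genes$alpha, 10, tolerance = 1e-3)
  expect_equal(est2$genes$beta, 2, tolerance = 1e-3)
  expect_equal(est2$genes$gamma, 0.5, tolerance = 1e-3)
  expect_equal(est2$genes$r2, 1, tolerance = 1e-6)
})

test_that("the special equal-rate branch of the splicing solution is
           continuous with the general branch", {
  g <- 1
  sol_gen <- dynofield:::model3_sol(1.5, 10, g * 1.01, g, u0 = 3, s0 = 7)
  sol_eq <- dynofield:::model3_sol(1.5, 10, g * 1.0001, g, u0 = 3, s0 = 7)
  expect_equal(sol_eq$s, sol_gen$s, tolerance = 0.02)
  expect_equal(sol_eq$u, sol_gen$u, tolerance = 0.02)
})

test_that("guesstimated starting values follow the log-ratio recipes", {
  # degradation: l halves over 1 h => gamma0 = log 2
  tt <- rep(c(0, 1), each = 10)
  l <- ifelse(tt == 0, 80, 40)
  lm <- layered_matrix(list(l = matrix(l, ncol = 1),
                            r = matrix(l + 10, ncol = 1)),
                       label_time = tt, experiment_type = "degradation")
  gg <- guesstimate_ranges(lm, 1)
  expect_equal(unname(gg$theta0["gamma"]), log(2))
  expect_equal(unname(gg$upper["gamma"]), 100 * log(2))
  expect_false(gg$fallback)
  # kinetics: l proportional to t => alpha0 = mean(l / t)
  tt2 <- rep(c(1, 2), each = 10)
  lm2 <- layered_matrix(list(l = matrix(5 * tt2, ncol = 1),
                             r = matrix(5 * tt2 + 20, ncol = 1)),
                        label_time = tt2, experiment_type = "kinetics")
  gg2 <- guesstimate_ranges(lm2, 1)
  expect_equal(unname(gg2$theta0["alpha"]), 5)
  # all-zero species: fallback with flag
  lm0 <- layered_matrix(list(l = matrix(0, 20, 1), r = matrix(0, 20, 1)),
                        label_time = tt, experiment_type = "degradation")
  gg0 <- guesstimate_ranges(lm0, 1)
  expect_true(gg0$fallback)
  expect_equal(unname(gg0$theta0["gamma"]), 1)
})

test_that("absolute splicing rate and velocities follow beta = gamma/gamma_tilde", {
  est <- dynofield:::new_kinetic_estimate("g1", "one-shot")
  est$genes$gamma <- 0.6
  out <- unify_beta(est, gamma_tilde = 0.3)
  expect_equal(out$genes$beta, 2.0)
  est$genes$gamma <- 0.7
  expect_equal(unify_beta(est, 1)$genes$beta, 0.7)   # gamma_tilde = 1
  # nonpositive gamma_tilde: gene skipped
  expect_true(is.na(unify_beta(est, -1)$genes$beta))
  # at labeling steady state l = (1 - exp(-gamma t)) alpha / gamma the
  # new-RNA velocity gamma l / (1 - exp(-gamma t)) - gamma l equals
  # alpha - gamma l
  gamma <- 0.7; alpha <- 5; t <- 2
  l <- (1 - exp(-gamma * t)) * alpha / gamma
  expect_equal(gamma * l / (1 - exp(-gamma * t)) - gamma * l,
               alpha - gamma * l)
})

test_that("labeled-fraction miscorrection biases gamma as printed", {
  expect_equal(labeling_bias(1, 0.5, 1)$delta_gamma, 0)
  b <- labeling_bias(0.8, 0.5, 1)
  expect_equal(b$delta_gamma, -log(0.6 / 0.5), tolerance = 1e-12)
  expect_equal(b$velocity_bias_sign, -1)
  expect_gt(labeling_bias(1.2, 0.5, 1)$delta_gamma, 0)
  expect_error(labeling_bias(2.5, 0.5, 1), "< 1")
})

test_that("burst statistics follow the negative-binomial relations", {
  bs <- burst_stats(mean_r = 10, var_r = 20, gamma = 0.5)
  expect_equal(bs$phi, 0.1)
  expect_equal(bs$bf, 5)
  expect_equal(bs$bs, 1)
  # Poisson gene (Var = mean) sits at the boundary and is flagged
  expect_true(burst_stats(10, 10, 0.5)$flagged)
})

test_that("goodness-of-fit metrics behave on exact and noisy fixtures", {
  x <- 1:20
  expect_equal(dynofield:::r_squared(x, x), 1)
  # Gaussian log-likelihood increases as noise decreases on a fixed fixture
  set.seed(11)
  truth <- 10 * (1 - exp(-0.5 * seq(0.2, 4, length.out = 50)))
  ll <- vapply(c(2, 1, 0.5, 0.1), function(sd_noise) {
    set.seed(11)
    dynofield:::gaussian_loglik(list(truth + rnorm(50, 0, sd_noise)),
                                list(truth))
  }, numeric(1))
  expect_true(all(diff(ll) > 0))
})

test_that("binomial mixture mass matches direct evaluation and limits", {
  expect_equal(mixture_likelihood(2, 10, 0.01, 0.1, 0),
               dbinom(2, 10, 0.01))
  expect_equal(mixture_likelihood(2, 10, 0.01, 0.1, 1),
               dbinom(2, 10, 0.1))
  expect_equal(mixture_likelihood(2, 10, 0.01, 0.1, 0.5),
               0.5 * dbinom(2, 10, 0.01) + 0.5 * dbinom(2, 10, 0.1))
  expect_error(mixture_likelihood(2, 10, 0.2, 0.1, 0.5), "identifiability")
})

test_that("velocity confidence metrics hit their boundary values", {
  set.seed(21)
  X <- matrix(rnorm(60 * 3), 60, 3)
  g <- knn_graph(X, K = 10)
  # zero velocity: neighborhood unchanged, Jaccard = 1
  J0 <- cell_velocity_confidence(X, X * 0, g, "jaccard")
  expect_true(all(J0 == 1))
  # velocities carrying one cluster onto a distant one: for the moved
  # cluster the current and future neighbor sets are disjoint, Jaccard = 0
  Xa <- cbind(seq(0, 5, length.out = 30), 0, 0)
  Xb <- cbind(seq(1000, 1005, length.out = 30), 0, 0)
  X2 <- rbind(Xa, Xb)
  V2 <- rbind(cbind(rep(1000, 30), 0, 0), matrix(0, 30, 3))
  g2 <- knn_graph(X2, K = 5)
  J2 <- cell_velocity_confidence(X2, V2, g2, "jaccard")
  expect_true(all(J2[1:30] == 0))
  expect_true(all(J2[31:60] == 1))
  # identical velocities: cosine consistency = 1
  V <- matrix(rep(c(1, 0, 0), each = 60), 60, 3)
  expect_equal(cell_velocity_confidence(X, V, g, "cosine"), rep(1, 60))
})

test_that("gene-wise confidence counts sign violations against the phase", {
  expr <- matrix(c(rep(0, 10), rep(5, 10)), ncol = 1)  # induced gene
  group <- rep(c("prog", "term"), each = 10)
  v_ok <- matrix(1, 20, 1)
  res <- gene_velocity_confidence(expr, v_ok, group, "prog", "term")
  expect_equal(unname(res$confidence[1, 1]), 1)
  expect_equal(unname(res$phase[1, 1]), 1)
  # half the cells violate strongly
  v_half <- matrix(rep(c(1, -1), 10), 20, 1)
  res2 <- gene_velocity_confidence(expr, v_half, group, "prog", "term")
  expect_equal(unname(res2$confidence[1, 1]), 0.5)
  expect_identical(res2$retained, character(0))
  # flat gene: phase undefined, confidence missing (not zero)
  flat <- matrix(1, 20, 1)
  res3 <- gene_velocity_confidence(flat, v_ok, group, "prog", "term")
  expect_true(is.na(res3$confidence[1, 1]))
  expect_error(gene_velocity_confidence(expr, v_ok, group, "nope", "term"),
               "unknown group")
})
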