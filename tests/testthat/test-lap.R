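test_that("the discrete action vanishes on field-aligned paths and scales
           with 1/D and the printed single-segment value", {
  f_const <- as_vectorfield(function(X) matrix(rep(c(2, 0), each = nrow(X)),
                                               nrow(X), 2),
                            jacobian = function(x) matrix(0, 2, 2), d = 2)
  # path moving exactly with the field: v_k = f(y_k) => S = 0
  dt <- 0.25
  path <- cbind(seq(0, 2, by = 2 * dt), 0)
  expect_equal(path_action(path, f_const, dt), 0)
  # single segment d = (1,0), f = (2,0): dt = 0.5 gives v = f => S = 0
  seg <- rbind(c(0, 0), c(1, 0))
  expect_equal(path_action(seg, f_const, 0.5), 0)
  # dt = 1: v = (1,0), residual 1 => S = 1/(2D)
  expect_equal(path_action(seg, f_const, 1, D = 1), 0.5)
  expect_equal(path_action(seg, f_const, 1, D = 0.5), 1)  # halve D, double S
  expect_error(path_action(seg, f_const, 0), "positive")
  # invariance under relabeling that preserves geometry and dt
  tf <- toggle_vectorfield()
  p <- cbind(seq(0.2, 2, length.out = 9), seq(1.9, 0.3, length.out = 9))
  expect_equal(path_action(p, tf, 0.3), path_action(p + 0, tf, 0.3))
})

test_that("the optimal time step matches its closed form", {
  f_const <- as_vectorfield(function(X) matrix(rep(c(2, 0), each = nrow(X)),
                                               nrow(X), 2),
                            jacobian = function(x) matrix(0, 2, 2), d = 2)
  seg <- rbind(c(0, 0), c(1, 0))
  expect_equal(optimal_dt(seg, f_const), 0.5)
  # scaling the field by 2 halves dt*
  f2 <- as_vectorfield(function(X) matrix(rep(c(4, 0), each = nrow(X)),
                                          nrow(X), 2),
                       jacobian = function(x) matrix(0, 2, 2), d = 2)
  expect_equal(optimal_dt(seg, f2), 0.25)
  # numeric minimizer agrees with the closed form on random fixtures
  tf <- toggle_vectorfield()
  set.seed(40)
  for (i in 1:3) {
    p <- matrix(runif(12, 0.2, 2.3), 6, 2)
    dt_star <- optimal_dt(p, tf)
    dt_num <- optimize(function(dt) path_action(p, tf, dt),
                       c(1e-4, 50), tol = 1e-10)$minimum
    expect_equal(dt_star, dt_num, tolerance = 1e-6)
  }
  f0 <- as_vectorfield(function(X) X * 0, jacobian = function(x) diag(0, 2),
                       d = 2)
  expect_error(optimal_dt(seg, f0), "vanishes")
})

test_that("the analytic action gradient matches central finite differences", {
  tf <- toggle_vectorfield()
  set.seed(41)
  for (rep in 1:3) {
    path <- matrix(runif(16, 0.2, 2.3), 8, 2)
    dt <- runif(1, 0.1, 1)
    g_ana <- dynofield:::action_gradient(path, tf, dt)
    h <- 1e-6
    for (k in 2:7) {
      for (a in 1:2) {
        pp <- path; pp[k, a] <- pp[k, a] + h
        pm <- path; pm[k, a] <- pm[k, a] - h
        g_num <- (path_action(pp, tf, dt) - path_action(pm, tf, dt)) / (2 * h)
        expect_equal(g_ana[k - 1, a], g_num, tolerance = 1e-6)
      }
    }
  }
})

test_that("least-action optimization behaves on gradient-flow fields", {
  # radial sink f = -x from (1,0) to (0,0): downhill, near-zero action
  f <- linear_field(diag(-1, 2))
  # downhill transitions have near-zero action and no unique optimum (the
  # motivation for the fastest-LAP search), so only the action's decay and
  # the path shape are asserted, not outer-loop convergence
  lap <- least_action_path(f, c(1, 0), c(0.01, 0), n_points = 15)
  expect_true(all(diff(lap$action_trace) <= 1e-12))
  expect_lt(lap$action, 0.01)
  expect_true(all(diff(lap$path[, 1]) < 1e-8))   # monotone in x1
  # the optimized path beats the same path traversed at a mismatched speed
  expect_lt(lap$action, path_action(lap$path, f, lap$dt * 3))
  # degenerate start = end
  lap0 <- least_action_path(f, c(1, 0), c(1, 0))
  expect_equal(lap0$action, 0)
})

test_that("toggle transitions are irreversible: uphill costs more than downhill", {
  tf <- toggle_vectorfield()
  fps <- find_fixed_points(tf, domain = rbind(c(0, 0), c(2.5, 2.5)),
                           n_seeds = 50, seed = 1)
  att <- fps[fps$type == "attractor", ]
  sad <- fps[fps$type == "saddle", ][1, ]
  a1 <- as.numeric(att[1, c("x1", "x2")])
  a2 <- as.numeric(att[2, c("x1", "x2")])
  s <- as.numeric(sad[c("x1", "x2")])
  # attractor -> saddle (uphill) vs saddle -> attractor (downhill)
  up <- least_action_path(tf, a1, s, n_points = 20)
  down <- least_action_path(tf, s, a1, n_points = 20)
  expect_gt(up$action, down$action)
  expect_gt(up$action, 0.01)
  expect_lt(down$action, 0.05)
  # attractor -> attractor forward and reverse differ
  fw <- least_action_path(tf, a1, a2, n_points = 20)
  rv <- least_action_path(tf, a2, a1, n_points = 20)
  # the symmetric toggle makes them equal in theory; perturb one threshold
  tfa <- toggle_vectorfield(a = c(1.4, 1))
  fpa <- find_fixed_points(tfa, domain = rbind(c(0, 0), c(2.7, 2.5)),
                           n_seeds = 60, seed = 2)
  atta <- fpa[fpa$type == "attractor", ]
  b1 <- as.numeric(atta[1, c("x1", "x2")])
  b2 <- as.numeric(atta[2, c("x1", "x2")])
  fw2 <- least_action_path(tfa, b1, b2, n_points = 20)
  rv2 <- least_action_path(tfa, b2, b1, n_points = 20)
  expect_gt(abs(fw2$action - rv2$action) /
            max(fw2$action, rv2$action), 0.05)
})

test_that("the fastest-LAP elbow search finds the knee of a convex curve", {
  f <- linear_field(diag(-1, 2))
  lap <- least_action_path(f, c(1.5, 0.5), c(0.01, 0.01), n_points = 15)
  fl <- flap(f, lap)
  expect_lte(fl$T_elbow, lap$traversal_time + 1e-9)
  expect_equal(length(fl$actions), 20)
  # action grows as the allowed time shrinks well below T*
  expect_gt(fl$actions[1], fl$actions[20])
  # one-point grid returns that point
  fl1 <- flap(f, lap, T_grid = lap$traversal_time / 2)
  expect_equal(fl1$T_elbow, lap$traversal_time / 2)
})

test_that("MSD ranking follows the printed cumulative-displacement formula", {
  path <- cbind(g_move = c(0, 0.5, 1), g_flat = c(2, 2, 2))
  rk <- msd_ranking(path)
  expect_equal(rk$msd[rk$gene == "g_move"], 0.25 + 1)
  expect_equal(rk$msd[rk$gene == "g_flat"], 0)
  expect_equal(rk$gene[rk$rank == 1], "g_move")
  # TF-restricted priority score S = 1 - R / #TF
  tfs <- sprintf("tf%03d", 1:133)
  pg <- matrix(0, 3, 133, dimnames = list(NULL, tfs))
  pg[, 1] <- c(0, 1, 2)      # tf001 moves most
  rk2 <- msd_ranking(pg, tf_list = tfs)
  expect_equal(rk2$priority[rk2$gene == "tf001"], 1 - 1 / 133)
  expect_equal(rk2$priority[rk2$gene == "tf001"], 0.9925, tolerance = 1e-4)
})

test_that("transition rates decay exponentially in the action", {
  st <- transition_stats(c(0, log(10)))
  expect_equal(st$rate[1], 1)
  expect_equal(st$rate[2], 0.1)
  expect_equal(st$mfpt[2], 10)
  st2 <- transition_stats(c(0, 0.5, 1, 2))
  expect_true(all(diff(st2$rate) < 0))
  expect_error(transition_stats(-1))
})

test_that("in-silico perturbations propagate through the Jacobian exactly", {
  # linear field with constant J = [[0,-1],[-1,0]], identity loadings
  f <- linear_field(rbind(c(0, -1), c(-1, 0)))
  f$X <- matrix(runif(20), 10, 2)
  emb <- list(loadings = diag(2), center = c(0, 0))
  rownames(emb$loadings) <- c("g1", "g2")
  # zero perturbation with zero center: zero response
  p0 <- perturb(f, emb, c(g1 = 0), X_cells = f$X)
  expect_true(all(p0$delta_f == 0))
  # delta_x = (1, 0) => delta_f = (0, -1) for every cell
  p1 <- perturb(f, emb, c(g1 = 1), X_cells = f$X)
  expect_equal(p1$delta_x, c(1, 0), ignore_attr = TRUE)
  expect_true(all(abs(sweep(p1$delta_f, 2, c(0, -1), "-")) < 1e-12))
  # back-transform consistency with Q = I, mu = 0: delta_g = delta_f
  expect_equal(unname(p1$delta_g), unname(p1$delta_f))
  expect_error(perturb(f, emb, c(nope = 1)), "absent")
  # suppressing x1 near the toggle saddle pushes flow toward the x2 attractor
  tf <- toggle_vectorfield()
  set.seed(42)
  cells <- matrix(runif(60, 0.8, 1.2), 30, 2)
  ps <- perturb(tf, emb, c(g1 = -100), X_cells = cells)
  expect_gt(mean(ps$delta_f[, 2] > 0), 0.5)      # majority sign test
  # mean subtraction applied exactly as specified, with an escape hatch
  emb_mu <- list(loadings = diag(2), center = c(0.5, 0.5))
  rownames(emb_mu$loadings) <- c("g1", "g2")
  pm <- perturb(f, emb_mu, c(g1 = 1), X_cells = f$X)
  expect_equal(pm$delta_x, c(1, 0) - c(0.5, 0.5), ignore_attr = TRUE)
  pnc <- perturb(f, emb_mu, c(g1 = 1), X_cells = f$X, centered = FALSE)
  expect_equal(pnc$delta_x, c(1, 0), ignore_attr = TRUE)
})
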