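test_that("toggle-switch fixed points are found, classified and verified", {
  tf <- toggle_vectorfield()
  dom <- rbind(c(0, 0), c(2.5, 2.5))
  fps <- find_fixed_points(tf, domain = dom, n_seeds = 50, seed = 1)
  expect_gte(nrow(fps), 3)
  expect_true(all(fps$norm_f < 1e-6))
  # the symmetric state (1,1) is a saddle with eigenvalues +-1
  i_saddle <- which.min((fps$x1 - 1)^2 + (fps$x2 - 1)^2)
  expect_equal(c(fps$x1[i_saddle], fps$x2[i_saddle]), c(1, 1),
               tolerance = 1e-6)
  expect_identical(fps$type[i_saddle], "saddle")
  ev <- attr(fps, "eigenvalues")[[i_saddle]]
  expect_equal(sort(Re(ev)), c(-1, 1), tolerance = 1e-6)
  # two off-diagonal attractors
  att <- fps[fps$type == "attractor", ]
  expect_equal(nrow(att), 2)
  # grid-minimization oracle for the attractor positions
  gx <- seq(0, 2.5, length.out = 251)
  grid <- as.matrix(expand.grid(gx, gx))
  nf <- sqrt(rowSums(toggle_field(grid)^2))
  for (i in seq_len(nrow(att))) {
    x_att <- c(att$x1[i], att$x2[i])
    near <- which(sqrt(rowSums(sweep(grid, 2, x_att, "-")^2)) < 0.15)
    best <- grid[near[which.min(nf[near])], ]
    expect_lt(sqrt(sum((best - x_att)^2)), 1e-2 + 1e-3)
  }
})

test_that("stability classes match the behavior of perturbed trajectories", {
  tf <- toggle_vectorfield()
  fps <- find_fixed_points(tf, domain = rbind(c(0, 0), c(2.5, 2.5)),
                           n_seeds = 50, seed = 1)
  set.seed(31)
  for (i in seq_len(nrow(fps))) {
    x0 <- c(fps$x1[i], fps$x2[i]) + runif(2, -0.02, 0.02)
    tr <- vf_trajectory(tf, x0, t_final = 20, n_steps = 100)
    end_dist <- sqrt(sum((tr$states[nrow(tr$states), ] -
                          c(fps$x1[i], fps$x2[i]))^2))
    if (fps$type[i] == "attractor") expect_lt(end_dist, 1e-3)
    if (fps$type[i] == "saddle") expect_gt(end_dist, 0.1)
  }
})

test_that("a linear sink yields one attractor with unit-negative spectrum", {
  f <- linear_field(diag(-1, 2))
  fps <- find_fixed_points(f, domain = rbind(c(-2, -2), c(2, 2)),
                           n_seeds = 20, seed = 2)
  expect_equal(nrow(fps), 1)
  expect_identical(fps$type, "attractor")
  expect_equal(c(fps$x1, fps$x2), c(0, 0), tolerance = 1e-8)
  expect_equal(Re(attr(fps, "eigenvalues")[[1]]), c(-1, -1))
})

test_that("nullcline continuation traces exact zero sets at the set spacing", {
  # f = (x - y, -y): the x-nullcline is the diagonal, fixed point at origin
  f <- as_vectorfield(function(X) cbind(X[, 1] - X[, 2], -X[, 2]),
                      jacobian = function(x) rbind(c(1, -1), c(0, -1)),
                      d = 2)
  fp <- data.frame(x1 = 0, x2 = 0)
  eps <- 0.02
  nls <- nullclines_2d(f, fp, eps = eps, max_points = 100,
                       domain = rbind(c(-1, -1), c(1, 1)), seed = 3)
  xnull <- Filter(function(b) attr(b, "component") == 1, nls)
  expect_gt(length(xnull), 0)
  for (b in xnull) {
    expect_true(all(abs(b[, 1] - b[, 2]) < 1e-6))   # on the diagonal
    # after the first (random-tangent) step, spacing locks to eps: the
    # arclength constraint measures along the previous tangent
    steps <- unname(sqrt(rowSums(diff(b)^2)))[-1]
    expect_equal(steps, rep(eps, length(steps)), tolerance = 1e-6)
  }
  # toggle x1-nullcline passes through every fixed point by definition
  tf <- toggle_vectorfield()
  fps <- find_fixed_points(tf, domain = rbind(c(0, 0), c(2.5, 2.5)),
                           n_seeds = 50, seed = 1)
  nl <- nullclines_2d(tf, fps, eps = 0.02, max_points = 200,
                      domain = rbind(c(0, 0), c(2.5, 2.5)), seed = 4)
  for (b in nl) {
    comp <- attr(b, "component")
    vals <- predict(tf, b)[, comp]
    expect_lt(max(abs(vals)), 1e-6)
  }
})

test_that("trajectory integration matches closed forms and stays put at roots", {
  f <- linear_field(diag(-1, 2))
  tr <- vf_trajectory(f, c(1, 0), t_final = log(2), n_steps = 50)
  expect_equal(tr$states[nrow(tr$states), ], c(0.5, 0), tolerance = 1e-6)
  # starting at the fixed point: constant trajectory
  tr0 <- vf_trajectory(f, c(0, 0), t_final = 5, n_steps = 20)
  expect_true(all(abs(tr0$states) < 1e-12))
  # basin membership: a state near the x1-high corner reaches that attractor
  tf <- toggle_vectorfield()
  tr_b <- vf_trajectory(tf, c(2.0, 0.3), t_final = 40, n_steps = 200)
  fin <- tr_b$states[nrow(tr_b$states), ]
  expect_gt(fin[1], fin[2])
  expect_lt(sqrt(sum(toggle_field(fin)^2)), 1e-4)
  # backward integration reverses the flow
  trf <- vf_trajectory(f, c(1, 0), t_final = 1, n_steps = 20)
  trb <- vf_trajectory(f, trf$states[20, ], t_final = 1, n_steps = 20,
                       direction = "backward")
  expect_equal(trb$states[20, ], c(1, 0), tolerance = 1e-5)
})

test_that("limit-cycle trimming drops repeated orbits but not transients", {
  # many uniform periods on the unit circle: last interval is redundant
  th <- seq(0, 16 * pi, length.out = 800)
  orbit <- structure(list(times = th, states = cbind(cos(th), sin(th)),
                          terminal = FALSE, truncated = FALSE,
                          trimmed_intervals = 0L), class = "Trajectory")
  trimmed <- trim_limit_cycles(orbit)
  expect_gte(trimmed$trimmed_intervals, 1)
  # monotone decay (still en route, not parked at the endpoint):
  # nothing removed
  tt <- seq(0, 4, length.out = 200)
  mono <- structure(list(times = tt,
                         states = cbind(3 * exp(-tt), 2 * exp(-tt)),
                         terminal = FALSE, truncated = FALSE,
                         trimmed_intervals = 0L), class = "Trajectory")
  expect_equal(trim_limit_cycles(mono)$trimmed_intervals, 0L)
  # white noise: spectra differ, nothing removed
  set.seed(32)
  noise <- structure(list(times = seq_len(200),
                          states = matrix(rnorm(400), 200, 2),
                          terminal = FALSE, truncated = FALSE,
                          trimmed_intervals = 0L), class = "Trajectory")
  expect_equal(trim_limit_cycles(noise)$trimmed_intervals, 0L)
})

test_that("the fate-probability formula reproduces hand-computed cases", {
  # 10 selected points, 2 beyond the cutoff, 3 move-backs: P = 8/13
  sel <- matrix(c(seq(0, 0.9, length.out = 8), 5, 6, rep(0, 10)), 10, 2)
  X_data <- matrix(c(seq(0, 0.9, length.out = 20), rep(0, 20)), 20, 2)
  groups <- rep("A", 20)
  p <- fate_probability_formula(sel, X_data, groups, move_back = 3,
                                dist_cutoff = 1)
  expect_equal(unname(p["A"]), 8 / 13)
  # all points within the cutoff, no move-backs: P = 1
  p1 <- fate_probability_formula(sel[1:8, , drop = FALSE], X_data, groups,
                                 move_back = 0, dist_cutoff = 1)
  expect_equal(unname(p1["A"]), 1)
  # a group whose cells are all far away scores 0
  X2 <- rbind(X_data, matrix(100, 5, 2))
  g2 <- c(groups, rep("B", 5))
  p2 <- fate_probability_formula(sel[1:8, , drop = FALSE], X2, g2,
                                 move_back = 0, dist_cutoff = 1)
  expect_equal(unname(p2["B"]), 0)
})

test_that("fate probabilities from toggle trajectories pick the right basin", {
  tf <- toggle_vectorfield()
  set.seed(33)
  X_data <- rbind(matrix(runif(200, 0, 1) + rep(c(1, 0), each = 100), 100, 2),
                  matrix(runif(200, 0, 1) + rep(c(0, 1), each = 100), 100, 2))
  groups <- rep(c("x1_high", "x2_high"), each = 100)
  tr <- vf_trajectory(tf, c(1.8, 0.4), t_final = 30, n_steps = 150)
  fp <- fate_probability(tr, tf, X_data, groups)
  expect_gt(fp$probabilities["x1_high"], fp$probabilities["x2_high"])
  expect_true(all(fp$probabilities >= 0 & fp$probabilities <= 1))
})

test_that("graph pseudotime orders sources before sinks", {
  # 1D chain with uniform rightward velocity
  X <- cbind(seq_len(30), 0)
  V <- cbind(rep(1, 30), 0)
  g <- knn_graph(X, K = 2)
  pt <- vf_pseudotime(X, V, g)
  expect_true(all(diff(pt$pseudotime) > 0))
  expect_equal(min(pt$pseudotime), 0)
  # pure rotation on a ring: the flow is curl-dominated, potential ~ flat
  th <- seq(0, 2 * pi, length.out = 41)[-41]
  Xr <- cbind(cos(th), sin(th))
  Vr <- cbind(-sin(th), cos(th))
  gr <- knn_graph(Xr, K = 2)
  ptr <- vf_pseudotime(Xr, Vr, gr)
  expect_lt(diff(range(ptr$pseudotime)), 0.3)
  # toggle samples: attractor cells sit later than saddle-adjacent ones
  tf <- toggle_vectorfield()
  set.seed(34)
  Xt <- matrix(runif(600, 0.05, 2.45), 300, 2)
  Vt <- toggle_field(Xt)
  gt <- knn_graph(Xt, K = 10)
  ptt <- vf_pseudotime(Xt, Vt, gt)
  near <- function(p, r = 0.3)
    sqrt(rowSums(sweep(Xt, 2, p, "-")^2)) < r
  saddle_cells <- near(c(1, 1))
  att_cells <- near(c(2, 0.3), 0.4) | near(c(0.3, 2), 0.4)
  expect_gt(mean(ptt$pseudotime[att_cells]),
            mean(ptt$pseudotime[saddle_cells]))
})
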