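#' Action of a discrete path in a stochastic dynamical system
#'
#' For dynamics `x' = f(x) + sigma eta(t)` with diffusion constant
#' `D = sigma^2 / 2`, the Onsager-Machlup-type action of a discrete path
#' `P = {x_0, ..., x_n}` with time step `dt` is
#' `S = 1/(2D) sum_k ||v_k - f(y_k)||^2 dt`, where
#' `v_k = (x_k - x_{k-1}) / dt` and `y_k = (x_{k-1} + x_k) / 2` are the
#' segment velocities and midpoints. Paths whose tangential velocity tracks
#' the field cost nothing.
#'
#' @param path (n+1) x d matrix of points, fixed endpoints included.
#' @param model a `VectorFieldModel` or `FunctionField`.
#' @param dt time step (> 0).
#' @param D diffusion constant (default 1).
#' @return the scalar action.
#' @export
path_action <- function(path, model, dt, D = 1) {
  path <- as.matrix(path)
  if (dt <= 0) stop("dt must be positive")
  stopifnot(nrow(path) >= 2)
  n <- nrow(path) - 1
  Vk <- (path[-1, , drop = FALSE] - path[-(n + 1), , drop = FALSE]) / dt
  Yk <- (path[-1, , drop = FALSE] + path[-(n + 1), , drop = FALSE]) / 2
  Fk <- predict(model, Yk)
  sum((Vk - Fk)^2) * dt / (2 * D)
}

#' Optimal time step for a fixed path
#'
#' Minimizing the action over `dt` alone has the closed form
#' `dt* = sqrt(sum ||d_k||^2 / sum ||f(y_k)||^2)` with segment
#' displacements `d_k = x_k - x_{k-1}`.
#'
#' @inheritParams path_action
#' @return the optimal `dt`.
#' @export
optimal_dt <- function(path, model) {
  path <- as.matrix(path)
  n <- nrow(path) - 1
  Dk <- path[-1, , drop = FALSE] - path[-(n + 1), , drop = FALSE]
  Yk <- (path[-1, , drop = FALSE] + path[-(n + 1), , drop = FALSE]) / 2
  Fk <- predict(model, Yk)
  sf <- sum(Fk^2)
  if (sf == 0) stop("field vanishes along the whole path: dt unbounded")
  sqrt(sum(Dk^2) / sf)
}

# exact gradient of the action with respect to the interior points.
# x_k enters v_k (+1/dt), v_{k+1} (-1/dt) and the midpoints y_k, y_{k+1}
# (weight 1/2 each), giving for component a of interior point k:
#   dS/dx_k^a = (1/D) (v_k^a - v_{k+1}^a + f^a(y_{k+1}) - f^a(y_k))
#     - (dt/2D) [ (v_k - f(y_k)) . J(y_k)[, a]
#               + (v_{k+1} - f(y_{k+1})) . J(y_{k+1})[, a] ]
action_gradient <- function(path, model, dt, D = 1) {
  path <- as.matrix(path)
  n <- nrow(path) - 1
  d <- ncol(path)
  Vk <- (path[-1, , drop = FALSE] - path[-(n + 1), , drop = FALSE]) / dt
  Yk <- (path[-1, , drop = FALSE] + path[-(n + 1), , drop = FALSE]) / 2
  Fk <- predict(model, Yk)
  Jk <- vf_jacobian(model, Yk)
  R <- Vk - Fk
  G <- matrix(0, n - 1, d)
  for (k in seq_len(n - 1)) {
    # segments k (between x_{k-1}, x_k) and k+1 (between x_k, x_{k+1})
    G[k, ] <- (Vk[k, ] - Vk[k + 1, ] + Fk[k + 1, ] - Fk[k, ]) / D -
      dt / (2 * D) * (drop(R[k, ] %*% Jk[, , k]) +
                      drop(R[k + 1, ] %*% Jk[, , k + 1]))
  }
  G
}

#' Least action path between two cell states
#'
#' Finds the most probable transition path between fixed endpoints by
#' alternating (i) the closed-form time-step update [optimal_dt()] and
#' (ii) quasi-Newton (L-BFGS-B) minimization of the action over the
#' interior points with the analytical gradient, until the relative action
#' change between outer iterations falls below `tol`. The path is
#' initialized with the interpolated shortest path on the kNN graph of the
#' model's training cells, falling back to linear interpolation when the
#' endpoints are off-manifold. Before optimizing, the analytic gradient is
#' checked against finite differences on a probe path; disagreement aborts
#' (it signals an implementation error, not a data problem).
#'
#' @param model a `VectorFieldModel` or `FunctionField`.
#' @param x_start,x_end endpoints (typically fixed points).
#' @param n_points path discretization (default 25 points).
#' @param D diffusion constant (default 1).
#' @param max_outer,tol outer alternation controls; the default declares
#'   convergence when the action changes by less than 1% between
#'   alternations (the action enters rates only through `exp(-S)`, so
#'   percent-level changes are immaterial, and the alternation contracts
#'   the remaining change geometrically).
#' @param maxit_inner L-BFGS-B iteration cap per outer step.
#' @param init optional initial path matrix overriding the default.
#' @param fixed_T optional fixed traversal time: `dt` is pinned to
#'   `fixed_T / n` instead of optimized.
#' @param grad_check run the finite-difference gradient self-check.
#' @return object of class `LAPResult`: list with `path`, `dt`, `action`,
#'   `traversal_time`, `n_outer`, `converged`, `action_trace`.
#' @export
least_action_path <- function(model, x_start, x_end, n_points = 25, D = 1,
                              max_outer = 20, tol = 1e-2,
                              maxit_inner = 500, init = NULL,
                              fixed_T = NULL, grad_check = TRUE) {
  d <- length(x_start)
  stopifnot(length(x_end) == d)
  if (is.null(init)) init <- init_path(model, x_start, x_end, n_points)
  path <- as.matrix(init)
  n <- nrow(path) - 1
  if (sum((x_start - x_end)^2) == 0) {
    return(structure(list(path = path, dt = 1e-2, action = 0,
                          traversal_time = 0, n_outer = 0L,
                          converged = TRUE, action_trace = numeric(0)),
                     class = "LAPResult"))
  }
  if (grad_check) check_action_gradient(model, path, D)
  dt <- if (is.null(fixed_T)) optimal_dt(path, model) else fixed_T / n
  S_old <- path_action(path, model, dt, D)
  trace <- S_old
  converged <- FALSE
  outer <- 0L
  for (outer in seq_len(max_outer)) {
    # (ii) path minimization at fixed dt
    obj <- function(par) {
      p <- path
      p[2:n, ] <- matrix(par, n - 1, d)
      path_action(p, model, dt, D)
    }
    grd <- function(par) {
      p <- path
      p[2:n, ] <- matrix(par, n - 1, d)
      as.vector(action_gradient(p, model, dt, D))
    }
    opt <- stats::optim(as.vector(path[2:n, ]), obj, grd, method = "L-BFGS-B",
                        control = list(maxit = maxit_inner))
    path[2:n, ] <- matrix(opt$par, n - 1, d)
    # (i) time-step minimization
    if (is.null(fixed_T)) dt <- optimal_dt(path, model)
    S_new <- path_action(path, model, dt, D)
    trace <- c(trace, S_new)
    if (abs(S_new - S_old) < tol * abs(S_old) + 1e-9) {
      converged <- TRUE
      S_old <- S_new
      break
    }
    S_old <- S_new
  }
  structure(list(path = path, dt = dt, action = S_old,
                 traversal_time = n * dt, n_outer = outer,
                 converged = converged, action_trace = trace),
            class = "LAPResult")
}

#' @exportS3Method print LAPResult
print.LAPResult <- function(x, ...) {
  cat(sprintf(
    "Least action path: %d points, action %.6g, traversal time %.4g (%d outer iterations%s)\n",
    nrow(x$path), x$action, x$traversal_time, x$n_outer,
    if (x$converged) "" else ", NOT converged"))
  invisible(x)
}

check_action_gradient <- function(model, path, D, probes = 3) {
  n <- nrow(path) - 1
  if (n < 2) return(invisible(TRUE))
  dt <- tryCatch(optimal_dt(path, model), error = function(e) 1)
  g_ana <- action_gradient(path, model, dt, D)
  g_scale <- max(abs(g_ana), 1e-8)
  # h large enough that kernel-coefficient cancellation noise (fields fitted
  # near the interpolation limit carry huge, canceling coefficients) stays
  # below the check's 1e-3 gate, small enough for negligible truncation
  h <- 1e-4 * max(1, max(abs(path)))
  set.seed(7)
  ks <- sample(2:n, min(probes, n - 1))
  for (k in ks) {
    for (a in seq_len(ncol(path))) {
      pp <- path; pp[k, a] <- pp[k, a] + h
      pm <- path; pm[k, a] <- pm[k, a] - h
      g_num <- (path_action(pp, model, dt, D) -
                path_action(pm, model, dt, D)) / (2 * h)
      # relative to the gradient scale: per-component ratios blow up at
      # near-zero components without indicating an implementation fault
      if (abs(g_num - g_ana[k - 1, a]) /
          max(abs(g_num), abs(g_ana[k - 1, a]), 1e-3 * g_scale) > 1e-3)
        stop("analytic action gradient disagrees with finite differences ",
             "(implementation error)")
    }
  }
  invisible(TRUE)
}

init_path <- function(model, x_start, x_end, n_points) {
  lin <- function() {
    s <- seq(0, 1, length.out = n_points)
    outer(1 - s, x_start) + outer(s, x_end)
  }
  X <- model$X
  if (is.null(X)) return(lin())
  # snap endpoints to cells and take the kNN-graph shortest path
  near <- knn_query(X, rbind(x_start, x_end), K = 1)
  g <- knn_graph(X, K = min(10L, nrow(X) - 1L))
  scale <- mean(g$distances)
  if (any(near$distances[, 1] > 5 * scale)) return(lin())  # off-manifold
  sp <- graph_shortest_path(g, near$indices[1, 1], near$indices[2, 1])
  if (is.null(sp)) return(lin())
  pts <- rbind(x_start, X[sp, , drop = FALSE], x_end)
  resample_path(pts, n_points)
}

# Dijkstra on the kNN graph (symmetrized)
graph_shortest_path <- function(g, from, to) {
  n <- nrow(g$indices)
  src <- rep(seq_len(n), g$K)
  dstv <- as.vector(g$indices)
  wts <- as.vector(g$distances)
  heads <- c(src, dstv)                 # symmetrize
  tails <- c(dstv, src)
  ws <- c(wts, wts)
  ord <- order(heads)
  heads <- heads[ord]; tails <- tails[ord]; ws <- ws[ord]
  first <- match(seq_len(n), heads)
  cnt <- tabulate(heads, n)
  dist <- rep(Inf, n); dist[from] <- 0
  prev <- rep(NA_integer_, n)
  visited <- rep(FALSE, n)
  for (iter in seq_len(n)) {
    u <- which.min(ifelse(visited, Inf, dist))
    if (!is.finite(dist[u])) break
    if (u == to) break
    visited[u] <- TRUE
    if (cnt[u] == 0) next
    rng <- first[u]:(first[u] + cnt[u] - 1L)
    for (r in rng) {
      v <- tails[r]; w <- ws[r]
      if (dist[u] + w < dist[v]) { dist[v] <- dist[u] + w; prev[v] <- u }
    }
  }
  if (!is.finite(dist[to])) return(NULL)
  path <- to
  while (!is.na(prev[path[1]])) path <- c(prev[path[1]], path)
  path
}

# resample a polyline to n equally spaced (by arclength) points
resample_path <- function(pts, n) {
  seg <- sqrt(rowSums(diff(pts)^2))
  cum <- c(0, cumsum(seg))
  if (max(cum) == 0) return(matrix(rep(pts[1, ], n), n, ncol(pts), byrow = TRUE))
  s <- seq(0, max(cum), length.out = n)
  out <- matrix(0, n, ncol(pts))
  for (j in seq_len(ncol(pts)))
    out[, j] <- stats::approx(cum, pts[, j], xout = s, ties = "ordered")$y
  out
}

#' Fastest least action path (elbow of action vs traversal time)
#'
#' For natural (downhill) transitions many near-zero-action paths exist and
#' the unconstrained LAP may pick an arbitrarily slow one. The path is
#' re-optimized at a grid of fixed traversal times `T < T*`; the normalized
#' action-vs-time curve is interpolated with a cubic spline and the elbow
#' `T^e` is the grid time closest to `T*` whose numerical second derivative
#' exceeds `curvature_frac` of the maximum curvature. A flat curve returns
#' `T* ` with a flag.
#'
#' @param model the field.
#' @param lap a converged [least_action_path()] result.
#' @param T_grid traversal times to scan; default 20 log-spaced values in
#'   `[T*/20, T*]`.
#' @param D diffusion constant.
#' @param curvature_frac elbow threshold as a fraction of max |curvature|.
#' @return list of class `FLAPResult`: `T_elbow`, `lap` (path at the
#'   elbow), `times`, `actions`, `flat` flag.
#' @export
flap <- function(model, lap, T_grid = NULL, D = 1, curvature_frac = 0.1) {
  stopifnot(inherits(lap, "LAPResult"))
  T_star <- lap$traversal_time
  if (is.null(T_grid))
    T_grid <- exp(seq(log(T_star / 20), log(T_star), length.out = 20))
  T_grid <- sort(T_grid)
  fits <- lapply(T_grid, function(Tt)
    least_action_path(model, lap$path[1, ], lap$path[nrow(lap$path), ],
                      n_points = nrow(lap$path), D = D, fixed_T = Tt,
                      init = lap$path, grad_check = FALSE))
  actions <- vapply(fits, function(f) f$action, numeric(1))
  if (length(T_grid) == 1)
    return(structure(list(T_elbow = T_grid, lap = fits[[1]], times = T_grid,
                          actions = actions, flat = FALSE),
                     class = "FLAPResult"))
  rng <- diff(range(actions))
  s_norm <- if (rng > 0) (actions - min(actions)) / rng else actions * 0
  sf <- stats::splinefun(T_grid, s_norm, method = "natural")
  tt <- seq(min(T_grid), max(T_grid), length.out = 200)
  curv <- abs(sf(tt, deriv = 2))
  thr <- curvature_frac * max(curv)
  flat <- max(curv) == 0 || rng == 0
  if (flat) {
    T_e <- T_star
    best <- lap
  } else {
    cand <- tt[curv > thr]
    T_e <- if (length(cand)) cand[which.min(abs(cand - T_star))] else T_star
    best <- fits[[which.min(abs(T_grid - T_e))]]
    T_e <- T_grid[which.min(abs(T_grid - T_e))]
  }
  structure(list(T_elbow = T_e, lap = best, times = T_grid,
                 actions = actions, flat = flat),
            class = "FLAPResult")
}

#' Gene ranking by mean square displacement along a path
#'
#' After projecting a path to gene space, each gene's cumulative squared
#' displacement from its starting value,
#' `MSD_i = sum_t (y_i(t) - y_i(0))^2`, measures how much that gene moves
#' along the transition; genes are ranked descending. When a transcription
#' factor list is given, ranking is restricted to it and the priority score
#' `S = 1 - R / #TF` is attached.
#'
#' @param path_genes points x genes matrix (a PCA path back-projected via
#'   loadings, or any gene-space path).
#' @param tf_list optional character vector restricting the ranking.
#' @return a `RankingTable` data.frame with `gene`, `msd`, `rank` and
#'   (with `tf_list`) `priority`.
#' @export
msd_ranking <- function(path_genes, tf_list = NULL) {
  path_genes <- as.matrix(path_genes)
  gn <- colnames(path_genes)
  if (is.null(gn)) gn <- sprintf("gene_%d", seq_len(ncol(path_genes)))
  msd <- colSums(sweep(path_genes, 2, path_genes[1, ], "-")^2)
  df <- data.frame(gene = gn, msd = msd, stringsAsFactors = FALSE)
  if (!is.null(tf_list)) df <- df[df$gene %in% tf_list, , drop = FALSE]
  ord <- order(-df$msd, df$gene)
  df <- df[ord, , drop = FALSE]
  df$rank <- seq_len(nrow(df))
  if (!is.null(tf_list)) df$priority <- 1 - df$rank / nrow(df)
  rownames(df) <- NULL
  class(df) <- c("RankingTable", "data.frame")
  df
}

#' Relative transition rate and mean first passage time from an action
#'
#' By the Freidlin-Wentzell large-deviation estimate the transition rate is
#' `R(A -> B) ~ C exp(-S*)` with an unknown proportionality constant `C`;
#' the mean first passage time is its reciprocal. Both are returned up to
#' `C` (i.e. `C = 1`), so only ratios between transitions are meaningful.
#'
#' @param action optimal-path action `S* >= 0` (vector ok).
#' @return data.frame with `rate = exp(-S*)` and `mfpt = exp(S*)`.
#' @export
transition_stats <- function(action) {
  stopifnot(all(action >= 0))
  data.frame(action = action, rate = exp(-action), mfpt = exp(action))
}
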