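#' Fixed points of a vector field
#'
#' Roots of `f(x) = 0` are searched by damped Newton iterations (with the
#' analytical Jacobian) started from Latin-hypercube seeds spread over a
#' bounded domain. Converged roots are deduplicated within a radius of
#' `dedup * mean(domain extents)` and classified by the signs of the
#' Jacobian eigenvalues at the root: all negative real parts = attractor,
#' all positive = repulsor, mixed (or zero) = saddle. When data states are
#' supplied, each fixed point gets a confidence `exp(-dist/l)` where `dist`
#' is the distance to the nearest observed cell and `l` the mean kNN
#' distance of the data (fields are least trustworthy far from cells).
#'
#' @param model a `VectorFieldModel` or `FunctionField`.
#' @param domain 2 x d matrix of lower/upper bounds (rows), or `NULL` to use
#'   the model's training-data bounding box.
#' @param n_seeds Latin-hypercube seed count (default 25).
#' @param tol root tolerance on `||f||` (default 1e-8); roots worse than
#'   1e-6 are discarded.
#' @param dedup deduplication radius as a fraction of domain scale.
#' @param X_conf optional data states for the confidence score.
#' @param seed RNG seed for the Latin-hypercube draw.
#' @return data.frame of class `FixedPointSet` with the positions
#'   (`x1..xd`), `type`, `norm_f`, `confidence`, plus an `eigenvalues`
#'   attribute (list).
#' @export
find_fixed_points <- function(model, domain = NULL, n_seeds = 25,
                              tol = 1e-8, dedup = 1e-2, X_conf = NULL,
                              seed = 0) {
  d <- field_dim(model)
  if (is.null(domain)) {
    X <- model$X
    if (is.null(X)) stop("supply `domain` for function fields")
    domain <- rbind(apply(X, 2, min), apply(X, 2, max))
  }
  domain <- as.matrix(domain)
  stopifnot(nrow(domain) == 2, ncol(domain) == d)
  scale <- mean(domain[2, ] - domain[1, ])
  set.seed(seed)
  seeds <- lhs::randomLHS(n_seeds, d)
  seeds <- sweep(sweep(seeds, 2, domain[2, ] - domain[1, ], "*"),
                 2, domain[1, ], "+")
  roots <- list()
  for (i in seq_len(n_seeds)) {
    x <- newton_root(model, seeds[i, ], tol = tol, max_iter = 100,
                     bound = domain, scale = scale)
    if (is.null(x)) next
    fx <- drop(predict(model, x))
    if (sqrt(sum(fx^2)) >= 1e-6) next
    # roots outside the search domain are extrapolation artifacts of the
    # decaying kernel field, not dynamics supported by data
    margin <- 0.02 * (domain[2, ] - domain[1, ])
    if (any(x < domain[1, ] - margin) || any(x > domain[2, ] + margin)) next
    dup <- FALSE
    for (r in roots) {
      if (sqrt(sum((x - r)^2)) < dedup * scale) { dup <- TRUE; break }
    }
    if (!dup) roots[[length(roots) + 1]] <- x
  }
  if (!length(roots)) {
    out <- data.frame(matrix(numeric(0), 0, d))
    names(out) <- paste0("x", seq_len(d))
    out$type <- character(0); out$norm_f <- numeric(0)
    out$confidence <- numeric(0)
    class(out) <- c("FixedPointSet", "data.frame")
    return(out)
  }
  P <- do.call(rbind, roots)
  evs <- vector("list", nrow(P))
  type <- character(nrow(P))
  for (i in seq_len(nrow(P))) {
    J <- vf_jacobian(model, P[i, ])[, , 1]
    ev <- eigen(J, only.values = TRUE)$values
    evs[[i]] <- ev
    re <- Re(ev)
    type[i] <- if (all(re < 0)) "attractor" else
      if (all(re > 0)) "repulsor" else "saddle"
  }
  confidence <- rep(NA_real_, nrow(P))
  if (is.null(X_conf) && !is.null(model$X)) X_conf <- model$X
  if (!is.null(X_conf)) {
    X_conf <- as.matrix(X_conf)
    Kc <- min(30L, nrow(X_conf) - 1L)
    ell <- mean(knn_graph(X_conf, K = Kc)$distances)
    nd <- knn_query(X_conf, P, K = 1)$distances[, 1]
    confidence <- exp(-nd / ell)
  }
  out <- as.data.frame(P)
  names(out) <- paste0("x", seq_len(d))
  out$type <- type
  out$norm_f <- vapply(seq_len(nrow(P)), function(i)
    sqrt(sum(predict(model, P[i, ])^2)), numeric(1))
  out$confidence <- confidence
  attr(out, "eigenvalues") <- evs
  class(out) <- c("FixedPointSet", "data.frame")
  out
}

field_dim <- function(model) {
  if (!is.null(model$d)) model$d else stop("cannot determine field dimension")
}

newton_root <- function(model, x0, tol, max_iter, bound, scale) {
  x <- x0
  for (it in seq_len(max_iter)) {
    fx <- drop(predict(model, x))
    nf <- sqrt(sum(fx^2))
    if (nf < tol) return(x)
    J <- vf_jacobian(model, x)[, , 1]
    step <- tryCatch(solve(J, -fx), error = function(e) NULL)
    if (is.null(step)) return(NULL)
    # damping: halve until ||f|| decreases
    lam <- 1
    repeat {
      xn <- x + lam * step
      fn <- sqrt(sum(predict(model, xn)^2))
      if (fn < nf || lam < 1e-6) break
      lam <- lam / 2
    }
    if (lam < 1e-6 && fn >= nf) return(NULL)
    x <- xn
    # abandon seeds escaping far outside the domain
    if (any(x < bound[1, ] - scale) || any(x > bound[2, ] + scale))
      return(NULL)
  }
  if (sqrt(sum(predict(model, x)^2)) < tol) x else NULL
}

#' Nullclines of a 2D vector field by pseudo-arclength continuation
#'
#' Starting from each fixed point (every nullcline passes through every
#' fixed point), the zero set of one field component is traced point by
#' point: the next point `p1` solves `f_comp(p1) = 0` together with the
#' arclength constraint `(p1 - p0) . v0 = eps`, where `v0` is the previous
#' tangent (a normalized random vector for the first step). Both directions
#' are traced until the domain is left or `max_points` is reached.
#'
#' @param model 2D `VectorFieldModel` or `FunctionField`.
#' @param fixed_points a [find_fixed_points()] result (or 2-column matrix).
#' @param eps arclength step.
#' @param max_points cap per branch.
#' @param domain 2 x 2 bounds matrix; default = data bounding box.
#' @param seed seed for first tangents.
#' @return list of polylines; each element is a matrix with attribute
#'   `component` (1 = x-nullcline, 2 = y-nullcline).
#' @export
nullclines_2d <- function(model, fixed_points, eps = 0.02, max_points = 500,
                          domain = NULL, seed = 0) {
  d <- field_dim(model)
  stopifnot(d == 2)
  P <- as.matrix(fixed_points[, 1:2])
  if (is.null(domain)) {
    X <- model$X
    if (is.null(X)) stop("supply `domain` for function fields")
    domain <- rbind(apply(X, 2, min), apply(X, 2, max))
  }
  set.seed(seed)
  out <- list()
  for (comp in 1:2) {
    for (i in seq_len(nrow(P))) {
      p0 <- P[i, ]
      v0 <- stats::rnorm(2); v0 <- v0 / sqrt(sum(v0^2))
      for (dir in c(1, -1)) {
        branch <- trace_nullcline(model, comp, p0, dir * v0, eps,
                                  max_points, domain)
        if (nrow(branch) > 1) {
          attr(branch, "component") <- comp
          out[[length(out) + 1]] <- branch
        }
      }
    }
  }
  out
}

trace_nullcline <- function(model, comp, p0, v0, eps, max_points, domain) {
  pts <- matrix(p0, 1, 2)
  p_prev <- p0; v_prev <- v0
  for (k in seq_len(max_points)) {
    # solve {f_comp(p) = 0 ; (p - p_prev).v_prev - eps = 0} by Newton
    p <- p_prev + eps * v_prev
    ok <- FALSE
    for (it in 1:50) {
      fp <- drop(predict(model, p))[comp]
      g2 <- sum((p - p_prev) * v_prev) - eps
      if (abs(fp) < 1e-10 && abs(g2) < 1e-12) { ok <- TRUE; break }
      Jrow <- vf_jacobian(model, p)[comp, , 1]
      A <- rbind(Jrow, v_prev)
      step <- tryCatch(solve(A, -c(fp, g2)), error = function(e) NULL)
      if (is.null(step)) break
      p <- p + step
    }
    if (!ok) break  # continuation stall: return partial polyline
    pts <- rbind(pts, p)
    v_new <- (p - p_prev) / sqrt(sum((p - p_prev)^2))
    p_prev <- p; v_prev <- v_new
    if (any(p < domain[1, ]) || any(p > domain[2, ])) break
  }
  pts
}

#' Integrate a trajectory in the vector field
#'
#' Adaptive explicit integration (via [deSolve::ode()], `ode45`-style);
#' `direction = "backward"` integrates `-f`. Trajectories escaping beyond
#' 10x the domain bound are truncated and flagged. Redundant limit-cycle
#' orbits are trimmed with [trim_limit_cycles()] when requested.
#'
#' @param model a `VectorFieldModel` or `FunctionField`.
#' @param x0 initial state.
#' @param t_final horizon (time units of the field).
#' @param n_steps number of output points.
#' @param direction `"forward"` or `"backward"`.
#' @param trim apply limit-cycle trimming.
#' @param domain_bound positive scalar; blow-up guard (default from data).
#' @return object of class `Trajectory`: list with `times`, `states`
#'   (T x d), `terminal` (logical: ended near zero velocity), `truncated`,
#'   `trimmed_intervals`.
#' @export
vf_trajectory <- function(model, x0, t_final = 10, n_steps = 200,
                          direction = c("forward", "backward"),
                          trim = FALSE, domain_bound = NULL) {
  direction <- match.arg(direction)
  stopifnot(all(is.finite(x0)))
  sgn <- if (direction == "forward") 1 else -1
  if (is.null(domain_bound)) {
    domain_bound <- if (!is.null(model$X)) max(abs(model$X)) else
      max(abs(x0), 1)
  }
  deriv <- function(t, y, parms) list(sgn * drop(predict(model, y)))
  times <- seq(0, t_final, length.out = n_steps)
  sol <- deSolve::ode(y = as.numeric(x0), times = times, func = deriv,
                      parms = NULL, method = "ode45")
  states <- unname(as.matrix(sol[, -1, drop = FALSE]))
  tt <- sol[, 1]
  truncated <- FALSE
  bad <- which(apply(abs(states), 1, max) > 10 * domain_bound)
  if (length(bad)) {
    keep <- seq_len(min(bad) - 1)
    states <- states[keep, , drop = FALSE]
    tt <- tt[keep]
    truncated <- TRUE
  }
  traj <- structure(list(times = tt, states = states,
                         terminal = FALSE, truncated = truncated,
                         trimmed_intervals = 0L),
                    class = "Trajectory")
  if (trim) traj <- trim_limit_cycles(traj)
  v_end <- sqrt(sum(predict(model, traj$states[nrow(traj$states), ])^2))
  v_start <- sqrt(sum(predict(model, traj$states[1, ])^2))
  traj$terminal <- v_end < 1e-3 * max(v_start, 1e-12) || v_end < 1e-8
  traj
}

#' Remove redundant limit-cycle orbits from a trajectory
#'
#' The trajectory is split into `k_intervals` equal blocks; the coordinate
#' series of the last two blocks are compared through their discrete
#' Fourier amplitude spectra. When `(1/m) || |F_{k-1}| - |F_k| ||` falls
#' below `threshold` the last block is a repeat of the previous orbit and
#' is dropped; the test repeats until it fails.
#'
#' @param traj a `Trajectory`.
#' @param k_intervals number of blocks (default 4).
#' @param threshold spectral-difference threshold (default 0.05).
#' @return the trimmed `Trajectory` with `trimmed_intervals` incremented.
#' @export
trim_limit_cycles <- function(traj, k_intervals = 4, threshold = 0.05) {
  stopifnot(inherits(traj, "Trajectory"))
  repeat {
    n <- nrow(traj$states)
    if (n < 2 * k_intervals) break
    m <- n %/% k_intervals
    blk <- function(j) traj$states[((j - 1) * m + 1):(j * m), , drop = FALSE]
    spec <- function(B) as.vector(apply(B, 2, function(col) Mod(stats::fft(col))))
    diffnorm <- sqrt(sum((spec(blk(k_intervals - 1)) -
                          spec(blk(k_intervals)))^2)) / m
    if (diffnorm >= threshold) break
    keep <- seq_len(n - m)
    traj$states <- traj$states[keep, , drop = FALSE]
    traj$times <- traj$times[keep]
    traj$trimmed_intervals <- traj$trimmed_intervals + 1L
  }
  traj
}

#' Fate probability of a predicted trajectory
#'
#' The low-speed tail of the trajectory is taken as the candidate terminal
#' region. If its points are not all within
#' `distance_threshold x median kNN distance` of observed cells, the window
#' is moved one step back along the trajectory (counting `move_back_steps`)
#' until they are, or the trajectory start is reached. For each cell group
#' the probability is then
#' `1 - (#(distances > threshold) + move_back) / (#selected + move_back)`,
#' clipped to `[0, 1]`, with distances measured from each selected point to
#' its nearest (or second-nearest, the default, to damp the influence of
#' single stray cells) cell of that group.
#'
#' @param traj a `Trajectory`.
#' @param model the field (for speeds along the trajectory).
#' @param X_data observed cell states; `groups` their labels.
#' @param speed_quantile tail definition: points with speed below this
#'   quantile of trajectory speeds (default 0.05).
#' @param distance_threshold multiplier on the median kNN distance.
#' @param use_second_nearest use the 2nd-nearest group cell (default TRUE).
#' @return object of class `FateProfile`: list with `probabilities`
#'   (named), `move_back_steps`, `n_selected`, `reached_data`.
#' @export
fate_probability <- function(traj, model, X_data, groups,
                             speed_quantile = 0.05, distance_threshold = 3,
                             use_second_nearest = TRUE) {
  X_data <- as.matrix(X_data)
  groups <- as.character(groups)
  states <- traj$states
  n_pts <- nrow(states)
  speeds <- sqrt(rowSums(predict(model, states)^2))
  thr <- stats::quantile(speeds, speed_quantile)
  below <- speeds <= thr
  run <- 0L  # trailing run of low-speed points
  for (i in rev(seq_len(n_pts))) { if (!below[i]) break; run <- run + 1L }
  tail_len <- min(max(run, 3L), n_pts)
  med_dist <- stats::median(knn_graph(X_data,
                                      K = min(2L, nrow(X_data) - 1L))$distances[, 1])
  move_back <- 0L
  start <- n_pts - tail_len + 1L
  repeat {
    sel <- states[start:(start + tail_len - 1L), , drop = FALSE]
    d_near <- knn_query(X_data, sel, K = 1)$distances[, 1]
    if (all(d_near <= distance_threshold * med_dist) || start <= 1L) break
    start <- start - 1L
    move_back <- move_back + 1L
  }
  reached <- all(knn_query(X_data, states[start:(start + tail_len - 1L), ,
                                          drop = FALSE],
                           K = 1)$distances[, 1] <= distance_threshold * med_dist)
  sel <- states[start:(start + tail_len - 1L), , drop = FALSE]
  out <- fate_probability_formula(sel, X_data, groups, move_back,
                                  distance_threshold * med_dist,
                                  use_second_nearest)
  structure(list(probabilities = out, move_back_steps = move_back,
                 n_selected = nrow(sel), reached_data = reached),
            class = "FateProfile")
}

#' Fate-probability formula on a selected point set
#'
#' The bare per-group probability
#' `1 - (#(distances > cutoff) + move_back) / (#selected + move_back)`
#' evaluated directly on given trajectory points; [fate_probability()]
#' performs the tail selection and move-back loop and then calls this.
#'
#' @param sel selected trajectory points (rows).
#' @param X_data observed cell states; `groups` their labels.
#' @param move_back number of move-back steps already taken.
#' @param dist_cutoff absolute distance cutoff.
#' @param use_second_nearest measure to the 2nd-nearest group cell.
#' @return named per-group probability vector.
#' @export
fate_probability_formula <- function(sel, X_data, groups, move_back,
                                     dist_cutoff, use_second_nearest = TRUE) {
  lev <- sort(unique(groups))
  sapply(lev, function(gl) {
    Xg <- X_data[groups == gl, , drop = FALSE]
    if (nrow(Xg) == 0) return(0)
    k <- if (use_second_nearest && nrow(Xg) >= 2) 2L else 1L
    dg <- knn_query(Xg, sel, K = k)$distances[, k]
    p <- 1 - (sum(dg > dist_cutoff) + move_back) /
      (nrow(sel) + move_back)
    min(max(p, 0), 1)
  })
}

#' Vector-field pseudotime by discrete Hodge-type potential extraction
#'
#' Velocities induce directed flows on the kNN graph: the flow on edge
#' (i, j) is the antisymmetrized cosine agreement between each endpoint's
#' velocity and the edge direction. A scalar potential `phi` is recovered
#' by least squares (`phi_j - phi_i ~ flow_ij`, a graph Poisson problem),
#' which annihilates the rotational flow component. Pseudotime is the
#' potential shifted to start at 0 (sources low, sinks high), computed per
#' connected component when the graph is disconnected (flagged).
#'
#' @param X cells x d states; `V` velocities; `g` a [knn_graph()].
#' @return object of class `PseudotimeResult`: list with `pseudotime`,
#'   `potential`, `n_components`.
#' @export
vf_pseudotime <- function(X, V, g) {
  X <- as.matrix(X); V <- as.matrix(V)
  n <- nrow(X)
  stopifnot(all(dim(X) == dim(V)), inherits(g, "NeighborGraph"))
  ii <- rep(seq_len(n), g$K)
  jj <- as.vector(g$indices)
  keep <- ii < jj  # undirected edge list (kNN symmetrized by union)
  extra <- which(!keep & !(paste(jj, ii) %in% paste(ii[keep], jj[keep])))
  e_i <- c(ii[keep], jj[extra]); e_j <- c(jj[keep], ii[extra])
  dedup <- !duplicated(paste(e_i, e_j))
  e_i <- e_i[dedup]; e_j <- e_j[dedup]
  m <- length(e_i)
  cosv <- function(a, b) {
    den <- sqrt(sum(a^2)) * sqrt(sum(b^2))
    if (den == 0) 0 else sum(a * b) / den
  }
  flow <- vapply(seq_len(m), function(e) {
    dx <- X[e_j[e], ] - X[e_i[e], ]
    (cosv(V[e_i[e], ], dx) - cosv(V[e_j[e], ], -dx)) / 2
  }, numeric(1))
  # least squares: minimize sum (phi_j - phi_i - flow)^2  => L phi = div
  B <- Matrix::sparseMatrix(i = rep(seq_len(m), 2), j = c(e_i, e_j),
                            x = c(rep(-1, m), rep(1, m)), dims = c(m, n))
  L <- Matrix::crossprod(B)
  rhs <- Matrix::crossprod(B, flow)
  comp <- graph_components(e_i, e_j, n)
  phi <- numeric(n)
  for (cid in unique(comp)) {
    idx <- which(comp == cid)
    if (length(idx) == 1) { phi[idx] <- 0; next }
    Lc <- L[idx, idx, drop = FALSE] +
      Matrix::Diagonal(length(idx), 1e-10)  # pin the additive constant
    phi[idx] <- as.numeric(Matrix::solve(Lc, rhs[idx]))
    phi[idx] <- phi[idx] - min(phi[idx])
  }
  n_comp <- length(unique(comp))
  if (n_comp > 1)
    warning("neighbor graph has ", n_comp,
            " components; potentials are per-component")
  structure(list(pseudotime = phi, potential = phi, n_components = n_comp),
            class = "PseudotimeResult")
}

graph_components <- function(e_i, e_j, n) {
  comp <- seq_len(n)
  find <- function(x) { while (comp[x] != x) { comp[x] <<- comp[comp[x]]; x <- comp[x] }; x }
  for (e in seq_along(e_i)) {
    a <- find(e_i[e]); b <- find(e_j[e])
    if (a != b) comp[a] <- b
  }
  vapply(seq_len(n), find, integer(1))
}
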