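#' Binomial mixture mass for labeling-induced nucleotide conversions
#'
#' Probability of observing `y` T-to-C conversions among `n` convertible
#' sites in a read, under a two-component binomial mixture: unlabeled reads
#' convert at the background rate `p_e`, labeled reads at the
#' labeling-induced rate `p_c`, and `pi_g` is the labeled fraction of the
#' gene's reads:
#' `P(y) = (1 - pi_g) B(y; n, p_e) + pi_g B(y; n, p_c)`.
#'
#' @param y conversion counts (vector ok); `n` site counts.
#' @param p_e,p_c background and labeling conversion rates, `0 <= p_e < p_c <= 1`.
#' @param pi_g labeled fraction in `[0, 1]`.
#' @return mixture probability mass, vectorized over `y`, `n`.
#' @export
mixture_likelihood <- function(y, n, p_e, p_c, pi_g) {
  if (p_e >= p_c) stop("p_e must be < p_c (identifiability)")
  stopifnot(all(y >= 0), all(y <= n), pi_g >= 0, pi_g <= 1)
  (1 - pi_g) * stats::dbinom(y, n, p_e) + pi_g * stats::dbinom(y, n, p_c)
}

#' EM fit of the binomial mixture to a read conversion table
#'
#' Estimates `(p_e, p_c, pi_g)` from per-read `(y, n)` summaries by
#' expectation-maximization on the collapsed (y, n) histogram. `p_e` may be
#' fixed from unlabeled control samples. Initial values `p_e = 0.004`,
#' `p_c = 0.02`, `pi = 0.5`; convergence when the log-likelihood changes by
#' less than `1e-6`, at most 1000 iterations.
#'
#' @param y,n integer vectors of conversions and convertible sites per read.
#' @param p_e_fixed optional fixed background rate.
#' @param init named list overriding the default initial values.
#' @param tol,max_iter EM controls.
#' @return object of class `MixtureQuantification`: list with `p_e`, `p_c`,
#'   `pi_g`, `loglik`, `n_iter`, `converged`.
#' @export
fit_mixture <- function(y, n, p_e_fixed = NULL, init = list(),
                        tol = 1e-6, max_iter = 1000) {
  stopifnot(length(y) == length(n), all(y >= 0), all(y <= n))
  # collapse to histogram for speed
  key <- paste(y, n)
  tab <- table(key)
  uy <- as.integer(sub(" .*", "", names(tab)))
  un <- as.integer(sub(".* ", "", names(tab)))
  wt <- as.numeric(tab)
  p_e <- if (!is.null(p_e_fixed)) p_e_fixed else
    if (!is.null(init$p_e)) init$p_e else 0.004
  p_c <- if (!is.null(init$p_c)) init$p_c else 0.02
  pi_g <- if (!is.null(init$pi_g)) init$pi_g else 0.5
  ll_old <- -Inf; converged <- FALSE; it <- 0
  for (it in seq_len(max_iter)) {
    d_e <- (1 - pi_g) * stats::dbinom(uy, un, p_e)
    d_c <- pi_g * stats::dbinom(uy, un, p_c)
    tot <- d_e + d_c
    tot[tot == 0] <- .Machine$double.xmin
    resp <- d_c / tot                       # P(labeled | read)
    ll <- sum(wt * log(tot))
    pi_g <- sum(wt * resp) / sum(wt)
    if (is.null(p_e_fixed)) {
      p_e <- sum(wt * (1 - resp) * uy) / max(sum(wt * (1 - resp) * un), 1e-12)
    }
    p_c <- sum(wt * resp * uy) / max(sum(wt * resp * un), 1e-12)
    if (p_e >= p_c) {  # keep components ordered
      tmp <- p_e; p_e <- min(p_c, tmp); p_c <- max(p_c, tmp)
      pi_g <- 1 - pi_g
    }
    if (is.finite(ll_old) && abs(ll - ll_old) < tol) {
      converged <- TRUE
      break
    }
    ll_old <- ll
  }
  structure(list(p_e = p_e, p_c = p_c, pi_g = pi_g, loglik = ll,
                 n_iter = it, converged = converged),
            class = "MixtureQuantification")
}

#' @exportS3Method print MixtureQuantification
print.MixtureQuantification <- function(x, ...) {
  cat(sprintf(
    "Binomial mixture fit: p_e = %.4g, p_c = %.4g, labeled fraction = %.3f (%d EM iterations%s)\n",
    x$p_e, x$p_c, x$pi_g, x$n_iter,
    if (x$converged) "" else ", NOT converged"))
  invisible(x)
}
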