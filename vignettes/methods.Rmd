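---
title: "Models and methods behind dynofield"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind dynofield}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dynofield)
```

`dynofield` estimates RNA kinetic rate constants and velocities from
single-cell data, reconstructs a continuous velocity vector field, and uses
the field's differential geometry for mechanistic predictions. This vignette
explains the models, the tunable parameters, the numerical choices made
where the methods literature leaves the design open, and the limits of what
the bundled simulations can demonstrate.

## 1. Kinetic models

Three nested ODE models describe a gene's RNA in a cell:

* **Splicing only** (conventional scRNA-seq):
  $\dot u = \alpha - \beta u$, $\dot s = \beta u - \gamma s$, with
  transcription rate $\alpha$ (molecules/h) and first-order splicing and
  degradation rate constants $\beta, \gamma$ (1/h). At pseudo-steady state
  $u = \tilde\gamma s$ with $\tilde\gamma = \gamma/\beta$ dimensionless, and
  the conventional velocity $v = u - \tilde\gamma s$ is *relative*: it
  carries units of molecules, not molecules per hour.
* **Labeling without splicing**: total RNA $r$ with
  $\dot r = \alpha - \gamma r$; RNA made during a labeling window of length
  $t$ is marked (efficiency $\rho$, assumed 1 after mixture correction), so
  at steady state $l = k\,r$ with $k = \rho(1 - e^{-\gamma t})$, giving the
  absolute $\gamma = -\ln(1-k)/t$ and the total-RNA velocity
  $\dot r = (\gamma/k)\,l - \gamma r$ in molecules/h.
* **Labeling with splicing**: the closed-form solutions for labeled
  unspliced/spliced species (and the decaying unlabeled species), including
  the degenerate $\beta = \gamma$ branch, are used by the nonlinear
  curve-fitting estimator. The branch is taken when
  $|\beta - \gamma|/\gamma < 10^{-3}$; the test suite checks continuity
  across the switch.

Combining the two routes, $\beta = \gamma/\tilde\gamma$ converts relative
splicing estimates into absolute ones (`unify_beta()`).

### Estimators and their assumptions

`fit_gamma_tilde_ss()` regresses $u$ on $s$ (zero intercept) over "extreme"
cells — the top 5% by $u+s$, minimum 10 cells — where the pseudo-steady-state
assumption is most plausible. `fit_gamma_tilde_gmm()` adds second moments:
the *stochastic* variant solves the master-equation moment conditions by
least squares; the *negative-binomial* variant exploits
$\mathrm{Var}(s) = \langle s\rangle + \phi\langle s\rangle^2$ with the
cell-wise reciprocal dispersion
$\hat\phi = (\mathrm{Var}(s)-\langle s\rangle)/\langle s\rangle^2$ and falls
back to the stochastic variant when $\hat\phi \le 0$ (underdispersion means
the NB premise fails).

For labeling slopes (`fit_one_shot()`, step 1 of `fit_two_step()`) the
extreme-cell score is the **regressor $r$ alone**, not $l + r$: conditional
on $r$ the labeled count has mean $k\,r$, so selecting on $r$ leaves the
zero-intercept slope unbiased, whereas a score that includes $l$ co-selects
the labeled-count noise and inflates $k$ by several percent — enough to bias
$\gamma$ visibly at a thousand cells. The same argument does not transfer
cleanly to the splicing plane (both $u$ and $s$ are noisy responses), so the
conventional estimators keep the standard $u+s$ corner.

Moment smoothing (`smooth_moments()`) averages each cell's counts over its
kNN neighborhood (default: 30 neighbors in 30 PCs, the cell included). For
designs with several labeling durations the averaging set is restricted to
cells sharing the duration; blending across time points mixes different
labeled/total regimes and biases the per-time slopes. One caveat the test
suite exposed: when the embedding is built from the *same one or two layers*
being regressed (as in a single-gene simulation), neighborhoods preserve
each cell's own noise and smoothing neither denoises nor debiases — with
many genes the embedding decouples from any single gene and smoothing
behaves as intended.

`fit_curve()` minimizes the weighted squared loss over species (labeled
weighted 2:1 over unlabeled, since unlabeled species follow degradation only
approximately) with multi-start Levenberg-Marquardt. Starts are
"guesstimated" from the data (log-ratio recipes in `guesstimate_ranges()`),
bounds are $(0, 100\,\theta_0)$, and the 20 Latin-hypercube draws are placed
log-uniformly over $[\theta_0/100,\ 100\,\theta_0]$ — rates span orders of
magnitude, and uniform draws over $(0, 100\,\theta_0)$ would almost never
probe small values. Ties between equally good optima go to the smaller
parameter norm. Goodness of fit is the standard $R^2$ for linear fits and a
Gaussian log-likelihood (species max-normalized) for curve fits; only its
monotonicity in noise is relied upon.

`burst_stats()` uses the negative-binomial identities
$BF = k_{on} = \gamma/\phi$ and $BS = \alpha/k_{off} = \langle r\rangle\phi$;
genes at or below the Poisson limit ($\mathrm{Var} \le$ mean) are flagged
rather than forced. These identities hold in the burst limit
$k_{off} \gg k_{on}, \gamma$; the exact telegraph-model variance
$\mu(1 + \alpha(1-p_{on})/(k_{on}+k_{off}+\gamma))$ deviates visibly outside
it (e.g. ~35% on $BF$ at $k_{on}=1$, $k_{off}=4$, $\gamma=0.5$), which is a
property of the approximation, not the estimator — the recovery tests
therefore run a deeply bursty regime. The binomial mixture model for conversion counts is fit
by EM on the collapsed $(y, n)$ histogram (init $p_e = 0.004$,
$p_c = 0.02$, $\pi = 0.5$; stop when the log-likelihood changes by less than
$10^{-6}$, at most 1000 iterations; $p_e$ optionally fixed from unlabeled
controls). The EM solution matches a direct maximum-likelihood oracle; at
10,000 reads the remaining $\pm 0.02$–$0.05$ spread in $\hat\pi$ is genuine
estimator variance from the overlap of the two binomial components, not an
optimization artifact.

## 2. Vector-field reconstruction

`fit_vectorfield()` learns $f(x) = \sum_j \Gamma(x, \tilde x_j)\,c_j$ with
Gaussian kernel $\Gamma(x,y) = e^{-w\|x-y\|^2}$ by sparse vector-field
consensus. Parameters, defaults and rationale:

| parameter | default | meaning |
|---|---|---|
| `m` | max(50, 5% of n) | control points, drawn uniformly without replacement (fixed seed) |
| `lambda` | 3 | RKHS regularization; smaller overfits, larger flattens |
| `w` | $1.5/(2 d_m)$ | inverse bandwidth; $d_m$ = mean distance to the nearest 20% of cells, so the kernel s.d. is $d_m/1.5$ |
| `a` | product of velocity ranges | outlier-domain volume; larger = laxer outlier calls |
| `max_iter`, `tol` | 500, $10^{-5}$ | EM stop on relative loss change |
| `q_init` | 0.9 | initial inlier fraction |

The EM alternates the inlier posterior
$p_i = \big(1 + \tfrac{1-q}{q}(2\pi\sigma^2)^{d/2}/a \cdot
e^{\|v_i - f(x_i)\|^2/2\sigma^2}\big)^{-1}$ with the weighted regularized
solve $(U^\top P U + \lambda\sigma^2 K)C = U^\top P V$ and the updates
$\sigma^2 = \sum_i p_i\|v_i - f(x_i)\|^2/(d\,\mathrm{tr}P)$,
$q = \mathrm{tr}P/n$. One design point deserves emphasis: the weighted
residual objective $\Phi = \tfrac{1}{2\sigma^2}\sum_i p_i\|v_i-f(x_i)\|^2 +
\tfrac{\lambda}{2}\|f\|_H^2$ is rescaled by every $\sigma^2$ update and is
provably non-monotone from a cold start ($\sigma^2$ shrinks by orders of
magnitude as the fit improves, inflating the $1/2\sigma^2$ factor faster
than residuals fall). The quantity EM actually descends is the negative
penalized observed-data log-likelihood; that is what `loss_trace` records,
what convergence tests, and what the non-increasing invariant is asserted
on. $\Phi$ is still exposed as `phi_trace`. The E-step uses the previous
iteration's field (standard EM ordering). Singular normal equations — which
arise legitimately on noiseless data once $\sigma^2$ hits its $10^{-12}$
floor — get a $10^{-8}$ ridge with a warning.

Control points translate with the data, so reconstruction is equivariant
under translation (tested). Model archives are RDS files with an explicit
format version: binary serialization is the only way to guarantee the
bit-for-bit round trip the evaluation contract demands.

## 3. Differential geometry and rankings

The Jacobian is analytic:
$J(x) = -2w\,C^\top K(x) D(x)$ with $K = \mathrm{diag}(\Gamma(x,\tilde x_j))$
and $D$ rows $x - \tilde x_j$. Divergence is $\mathrm{tr}\,J$, acceleration
$Jv$, curvature $\kappa = (Jv(v\cdot v) - v(v\cdot Jv))/\|v\|^4$; in 2D the
triple-product form is computed as well and the two are asserted to agree to
$10^{-10}$ (they are algebraically identical by the BAC-CAB identity).
Curvature at a zero-velocity point is undefined and reported missing.
Gene-space projection $G = QJQ^\top$ is evaluated per requested gene pair so
the $d_{genes}^2$ matrix is never materialized. Rankings average raw or
absolute values per cluster with ties broken by gene identifier;
toggle-switch pair scores gate $K = JJ^\top$ by mutual inhibition with
Iverson brackets. Hill-derivative fits pool cells into 20 equal-count
expression bins and weight bin means by inverse bin s.d.; the degradation
offset $\gamma$ is free only for self-interactions.

## 4. Topology and paths

Fixed points: damped Newton (analytic Jacobian) from 25 Latin-hypercube
seeds by default, roots accepted at $\|f\| < 10^{-6}$, deduplicated within
$10^{-2}$ of the domain scale, classified by Jacobian eigenvalue signs.
Confidence decays exponentially with the distance to the nearest observed
cell over the mean kNN distance — fields are extrapolations far from data.
Nullclines follow pseudo-arclength continuation from each fixed point with a
random first tangent (fixed seed) and Newton corrections on the pair
{component zero, arclength constraint}.

Trajectories integrate with `deSolve` (ode45); backward integration flips
the field; states escaping ten times the data bound truncate the trajectory
with a flag. Limit-cycle trimming splits the trajectory into 4 blocks and
compares the **moduli** of the discrete Fourier spectra of the last two
blocks (threshold 0.05): consecutive orbits of the same cycle differ only by
a time shift, i.e. per-bin phase factors, so the modulus is the
shift-invariant comparison; complex spectra would depend on where the block
boundaries happen to fall.

Fate probabilities follow the tail-selection / move-back procedure with the
final formula
$1 - (\#\{d > \tau\cdot\mathrm{med}\} + \mathrm{moveback}) /
(\#\mathrm{selected} + \mathrm{moveback})$, distances taken to each group's
second-nearest cell (switchable to nearest); the speed threshold is the 5th
percentile of speeds along the trajectory. Pseudotime solves the graph
Poisson problem $\phi_j - \phi_i \approx \omega_{ij}$ for the
antisymmetrized cosine edge flows — the least-squares potential annihilates
the rotational component, which is why a pure rotation yields a flat
potential (tested).

The discrete action
$S = \tfrac{1}{2D}\sum_k \|v_k - f(y_k)\|^2\,\Delta t$ (midpoints $y_k$,
$D = \sigma^2/2$, default 1) is minimized by alternating the closed-form
time step $\Delta t^* = \sqrt{\sum\|d_k\|^2 / \sum\|f(y_k)\|^2}$ with
L-BFGS-B over the interior points using the exact analytic gradient
$$\partial S/\partial x_k^a = \tfrac{1}{D}\big(v_k^a - v_{k+1}^a +
f^a(y_{k+1}) - f^a(y_k)\big) - \tfrac{\Delta t}{2D}\big[(v_k - f(y_k))\cdot
J(y_k)_{\cdot a} + (v_{k+1} - f(y_{k+1}))\cdot J(y_{k+1})_{\cdot a}\big],$$
which is the derivative of the midpoint-discretized action (the
finite-difference oracle in the test suite pins it to $10^{-6}$ relative).
Before any optimization the gradient is self-checked against finite
differences on a probe path and the run aborts on disagreement, since that
can only mean an implementation fault. The outer alternation stops when the
action changes by less than 1%: the action enters predictions only through
$e^{-S}$, the alternation contracts the remaining change geometrically
(roughly threefold per round), and at this tolerance the benchmark
transitions converge in two to three alternations. Paths are initialized
from the interpolated kNN-graph shortest path between the snapped endpoints,
falling back to a straight line off-manifold. The fastest-LAP search
re-optimizes at 20 log-spaced traversal times in $[T^*/20, T^*]$, splines
the normalized action curve, and takes the elbow as the time nearest $T^*$
whose curvature exceeds 10% of the maximum.

In-silico perturbations apply $\Delta x = c\,Q^\top(\Delta y - \mu)$,
$\Delta f = J(x)\Delta x$, $\Delta g = Q\Delta f + \mu$. The mean
subtraction is applied exactly as the transform is defined even though a
difference vector arguably needs no centering; `centered = FALSE` provides
the uncentered alternative without guessing intent.

## 5. What the simulations do and do not show

`simulate_expression()` is an exact SSA of the two-state promoter with
transcription, optional splicing, degradation and labeling; burn-in is
$10/\gamma$ (capped at 1000 h) and degradation designs label for $5/\gamma$
before the chase. Parameter-recovery tests run the *constitutive* promoter
at $n = 1000$ cells: the labeling estimators assume a constant transcription
rate, so that regime is their stated operating condition, while the bursty
regime ($k_{on} = 1$, $k_{off} = 4$/h) exercises the burst statistics. The
toggle-switch benchmark samples 5,000 states uniformly on $[0, 2.5]^2$; the
downsampled (312 cells) and noisy (velocity noise at 50% of mean speed)
variants probe robustness. Test problem sizes (1,000–5,000 cells, 10 genes,
2-D fields, 25-point paths) were chosen as the smallest scales at which the
estimators' asymptotic behavior is visible.

What passing these tests does **not** show: real data have batch effects,
cell-cycle structure, gene-specific capture efficiencies, non-constant
rates, and velocity errors that are correlated across genes — none of which
the generator emulates. Reconstructions in more than a few dimensions face
kernel-bandwidth and sampling-density issues the 2-D benchmark cannot
expose, and fate probabilities inherit every bias of the embedding in which
the field was learned. Jacobian signs are regulatory *associations* under
the learned field, not causal claims.

## 6. Known limitations

* The extreme-cell device assumes the top expression quantile is at steady
  state; systems far from steady state bias all slope-based estimators.
* The NB moment estimators need genuine overdispersion; near-Poisson genes
  fall back or are flagged.
* `fit_curve()` with coarse time grids cannot resolve fast splicing
  ($\beta \gg 1/t$); combine with splicing-based $\tilde\gamma$ instead.
* Exact kNN is quadratic in cells; it is deterministic (ties by index) and
  fine at desk scale, but a different backend would be needed far beyond
  $10^4$ cells.
* The uniform-outlier volume `a` is a blunt instrument: extremely large
  values disable outlier rejection entirely (by design).
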