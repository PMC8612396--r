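---
title: "Constrained parsimonious model-based clustering with parsmix"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Constrained parsimonious model-based clustering with parsmix}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(parsmix)
```

## The model

parsmix fits a `k`-component Gaussian mixture to an `n x p` data matrix by
maximising either the mixture log-likelihood (EM) or the classification
log-likelihood over hard partitions (CEM). Both targets are unbounded when
the component covariances are unrestricted: a component that collapses onto
a few nearly collinear points drives its smallest eigenvalue to zero and
the likelihood to infinity, producing the familiar "spurious solutions".
The classical remedy is to pick one of the 14 parsimonious covariance
structures (EII, ..., VVV), which either constrains hard (exact equality
of volumes, shapes or orientations) or not at all.

This package instead works on the decomposition

$$\Sigma_j = d_j\, R_j\, D_j\, R_j', \qquad
  d_j = |\Sigma_j|^{1/p},\quad |D_j| = 1,\quad R_j'R_j = I,$$

with `d_j` the volume, `D_j = diag(g_{j1}, ..., g_{jp})` the
unit-determinant shape and `R_j` the rotation, and bounds three ratios by
tunable constants, all `>= 1`:

* **determinant** — `max_j |Sigma_j| / min_j |Sigma_j| <= c_det`;
* **shape-within** — `max_l g_{jl} / min_l g_{jl} <= c_shw` for every `j`
  (1 forces spherical components);
* **shape-between** — `max_j g_{jl} / min_j g_{jl} <= c_shb` for every
  coordinate `l` (1 forces a common shape).

A rotation regime completes the specification: `I` (axes aligned with the
coordinates), `E` (one common rotation) or `V` (free rotations, in which
case each component's shape elements are kept in non-increasing order so
the decomposition is identifiable). Any finite choice of the constants
yields a well-defined maximisation; pushing each constant to 1 or infinity
recovers the 14 classical models as limit cases (`limit_models()` lists
the mapping). The raw enumeration has `2^3 * 3 = 24` combinations; those
with `c_shw = 1` but `c_shb > 1` are infeasible and sphericity makes the
rotation immaterial, which leaves exactly 14.

A useful algebraic fact links the two shape constraints: unit-determinant
shapes whose within-ratio is at most `c_shw` can never produce an
(order-statistic) between-ratio above `c_shw^((p-1)/p)`, so `c_shb` is
capped at that bound (`shb_bound()`). One caveat we document because it is
easy to miss: the bound is a statement about *sorted* shape vectors. In
the `I`/`E` regimes, where shape elements live in shared coordinates, the
unsorted ratio can reach `c_shw^(2(p-1)/p)`; the cap is applied in every
regime regardless, since values of `c_shb` above it describe essentially
unconstrained between-shape behaviour.

## The fitting algorithm

`parsmix()` runs a nested ECM. Each outer iteration computes observation
weights (posterior probabilities, or one-hot indicators for CEM with ties
going to the lowest component index), updates the weights and means in
closed form, and then updates the covariances under the constraints. The
covariance update cycles three blocks until the largest relative change
falls below `tol_ddr`:

1. **Shape.** Starting from the scaled diagonals
   `diag(R_j' S_j R_j) / d_j` of the weighted covariances `S_j`, an inner
   loop applies the within-constraint by *optimal truncation* (see below)
   with unit weights, applies the between-constraint coordinate-wise with
   the component masses `n_j` as weights (after sorting under free
   rotations), and renormalises each shape to unit determinant. Both
   truncations act on the raw scaled diagonals, which makes each
   truncation the exact conditional optimum coordinate-wise and
   reproduces the classical estimators at the limit configurations; when,
   for intermediate `c_shb`, the final renormalisation leaves a
   between-ratio marginally above the constant, a normalise-first pass
   (a no-op at all limit cases) restores exact feasibility.
2. **Volume.** The unconstrained optimum is
   `nu_j = trace(D_j^{-1} R_j' S_j R_j) / p`; optimal truncation at
   `c_det^(1/p)` with weights `n_j` enforces the determinant constraint.
3. **Rotation.** Under `rot = "E"` the common rotation is improved by
   majorisation-minimisation of
   `sum_j n_j/(n d_j) trace(D_j^{-1} R' S_j R)`: with
   `W_j = (n_j/n) S_j` and `omega_j` just above the largest eigenvalue of
   `W_j`, each step maximises `trace(R' G)` for
   `G = sum_j d_j^{-1} (omega_j I - W_j) R D_j^{-1}` via the singular
   value decomposition of `G`. Taking `omega_j` *strictly* above the top
   eigenvalue keeps the majorisation valid while making `G` full rank, so
   the optimum is an exact, unique fixed point. A guard stops the loop in
   the (numerically impossible, by construction) event that an iterate
   worsens the objective. Under `rot = "I"` and `rot = "V"` no rotation
   work is needed.

Convergence of every loop is monitored by the maximal per-component
relative change `||vec(b_j) - vec(b_j_prev)|| / ||vec(b_j_prev)||`
(`relative_change()`); rotations use the dedicated monitor
`|p - trace((R'R_prev)'(R R_prev'))| / p`, which is quadratic in the
rotation angle — worth knowing when choosing `tol_rot`, since a tolerance
of `1e-12` corresponds to an angular accuracy near `1e-6`.

Each of `nstart` starts draws `k (p + 1)` observations, splits them into
`k` groups, and uses the group means and covariances as initial
parameters (singular group covariances receive a diagonal ridge
`1e-6 tr(S)/p I`; with fewer than `k(p+1)` observations the draw falls
back to resampling). The constraints are imposed from the first M-step
on. A CEM start that empties a component is aborted and logged rather
than silently continuing with fewer components; `n_starts_ok` reports how
many starts survived. Per-start sub-seeds are derived from the master
seed, so results are reproducible and independent of evaluation order.

### The optimal-truncation operator

All three constraints are imposed by one primitive, `opt_trunc()`:
given non-negative values `v_j` and weights `w_j`, clamp into `[t, c t]`
where `t` minimises `f(t) = sum_j w_j (log m_t(v_j) + v_j / m_t(v_j))`.
The minimiser is located exactly: `t*` is either a point where the
clamping pattern changes (`v_j` or `v_j / c`) or the stationary value
`t = (sum_L w v + c^{-1} sum_U w v) / sum_{L+U} w` inside an interval
with a fixed pattern; all candidates are evaluated. At `c = 1` the
operator returns the weighted mean; at `c = Inf` it is the identity. A
task whose positive-weight values are all zero signals a degenerate
(collapsed) component to the caller. When a scatter is singular but every
relevant constant is infinite — the genuinely unbounded case — volumes
and shapes are floored at `1e-12` of the largest value rather than left
at zero.

## Model selection

The criterion is `BIC = -2 L + v log n`, minimised, with the penalty

$$v = kp + (k-1) + \Big[(k-1)\big(1 - c_{det}^{-1/p}\big) + 1\Big]
  + (p-1)\Big(1 - \tfrac{1}{c_{shw}}\Big)
    \Big[(k-1)\Big(1 - \tfrac{1}{c_{shb}}\Big) + 1\Big]
  + k(\mathrm{rot})\,\tfrac{p(p-1)}{2},$$

where `k(rot)` is 0, 1 or `k` for `I`, `E`, `V`. The penalty is not a
parameter count in general — it grades the *flexibility* the constraints
allow — but it coincides exactly with the classical free-parameter count
at each of the 14 limit configurations, which the tests verify for every
`(k, p)` in `{1..5} x {2..6}`.

`parsmix_select()` searches in two phases, restricting constants to
powers of two. Phase 1 fits every `k` in `1..k_max` against the 14 limit
patterns with infinity replaced by the mildly-constraining `2^(c_levels-1)`
(slightly constrained rather than unbounded, which also avoids
singularities); the BIC-best configuration fixes `k`, the rotation and any
constant equal to 1. For `k = 1`, patterns that differ only in vacuous
constants share one fit but all 14 rows are kept in the table. Phase 2
refines the remaining constants over `2^0 .. 2^(c_levels-1)`, capped by
the phase-1 values and the between/within bound (infeasible triples are
never evaluated), warm-starting each fit with the phase-1 winner as one
extra start — which can only improve the maximised target. BIC ties go to
the smaller penalty, then the smaller `k`.

## Synthetic data and overlap control

Two fixed benchmark designs are built in. `sim_design_a()` draws three
bivariate normals with means `(0,0)`, `(2,6)`, `(6,0)` and covariances
`diag(2,2)`, `diag(3,1)`, `diag(1,2)`, sizes `(50, 20, 20)` (doubled under
`higher_n`), plus one or two independent `N(0, 100)` noise coordinates —
a setting where unconstrained fits are unstable because the noise
dominates the scale. `sim_design_b()` draws six spherical bivariate
clusters with printed means and sizes `(23, 36, 93, 38, 123, 12)` plus
the same noise coordinate. The in-plane variance of design B is not
pinned down by its source; we use 1, consistent with visibly separated
spherical clusters several units apart.

`sim_overlap_mixture()` generates random parameters whose covariances
satisfy a chosen pattern *by construction* — volumes log-uniform within
the allowed determinant ratio, shapes drawn at random and passed through
the same truncation operators the fitter uses, rotations Haar-uniform —
and whose average pairwise overlap hits a prefixed target. Overlap is the
sum of the two directed misclassification probabilities
`w[j|l] = P(pi_l phi_l(X) < pi_j phi_j(X))`, `X ~` component `l`,
averaged over pairs (`pairwise_overlap()`, Monte Carlo with common random
numbers inside the calibration). The target is reached by scaling the
mean configuration about its centroid — chosen over covariance inflation
because it leaves the covariance pattern untouched — with the scale found
by bisection (tolerance 0.002 by default, against `1e5` verification
draws the realised rate is within about 0.005 of the target). For limit
patterns the infinite constants are replaced by finite surrogates, 100
for determinant/within and 10 for between, so the generated matrices vary
but stay tame. Two practical notes: highly eccentric draws in higher
dimension can saturate below the target even with coincident means, in
which case the generator redraws the configuration (up to 20 times)
rather than failing; and the Monte-Carlo estimator, not the exact
Gaussian quadratic-form distribution, is used throughout — the
one-dimensional closed form (normal tails beyond the midpoint) anchors
its correctness in the tests.

## Numerical choices worth knowing

* Densities are evaluated through the Cholesky factor of each covariance
  in log space; underflow cannot zero out a posterior row.
* Default controls: `nstart = 50`, `iter_max = 100`, inner iteration caps
  20, all tolerances `1e-6`. Simulation studies in the literature
  typically use `nstart = 1000`; raise it when hunting global optima.
* Eigen problems use symmetric solvers with a deterministic sign
  convention; exact E-step ties go to the lowest component index —
  both choices make runs byte-reproducible.
* The constraint report attached to a fit uses a tolerance of ten times
  `tol_ddr`, since the inner loops only enforce the constraints up to
  their own convergence tolerance.
* The per-start ECM loop is compiled (RcppArmadillo); the model search
  fits on the order of `14 k_max + c_levels^3` configurations, which in
  pure R would dominate interactive use.

## What the simulations do and do not show

The built-in designs exercise exactly the failure mode the constraints
target — a large-variance noise direction that lures unconstrained fits
into spurious solutions — and the overlap-controlled generator produces
calibrated-difficulty mixtures whose covariances obey a known pattern.
Passing tests on these designs demonstrates correct mechanics
(constraint satisfaction, monotone targets, limit-case equivalence,
recovery of `k` at moderate overlap); they do not demonstrate robustness
to outliers or non-Gaussian components (no trimming is implemented),
performance under `n < p`, or anything about missing data, which the
package does not handle. The test suite runs the selection experiment at
`nstart = 50` over 10 replicates and the consistency comparison at
`n = 90` versus `n = 180` over 30 replicates — sizes chosen as a
representative scaled-down version of the corresponding published-style
experiments.

## A worked example

```{r, eval = FALSE}
library(parsmix)

data <- sim_design_a(seed = 1)
fit <- parsmix(data[1:3], k = 3, c_det = 2, c_shw = 100, c_shb = 2,
               control = parsmix_control(nstart = 50), seed = 1)
glance(fit)
adjusted_rand_index(fit$labels, data$component)

sel <- parsmix_select(data[1:3], k_max = 5, c_levels = 6, seed = 1)
glance(sel)
autoplot(sel)
```
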