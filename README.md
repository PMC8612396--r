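# parsmix

Constrained parsimonious model-based clustering: Gaussian mixtures whose
component covariance matrices are restricted by *tunable* constants rather
than by all-or-nothing structural choices.

## The problem

Maximum-likelihood Gaussian mixture clustering is haunted by two facts:
the likelihood is unbounded (a component collapsing onto a few nearly
collinear points sends it to infinity), and the classical escape — the 14
parsimonious models coded EII … VVV — only offers the extremes "exactly
equal" or "completely free" for each covariance feature. parsmix fills
the gap. Writing each scatter matrix as

```
Sigma_j = d_j R_j D_j R_j',   d_j = |Sigma_j|^(1/p),  |D_j| = 1,  R_j orthogonal
```

(volume × rotation × unit-determinant shape), it bounds

* `max_j |Sigma_j| / min_j |Sigma_j|  <= c_det` (volumes),
* `max_l g_jl / min_l g_jl            <= c_shw` per component (shape within),
* `max_j g_jl / min_j g_jl            <= c_shb` per coordinate (shape between),

for constants `>= 1`, combined with a rotation regime `rot` in `{I, E, V}`
(axis-aligned, equal, free). Every finite choice gives a well-defined,
spurious-solution-resistant problem; the constants' limits (1 or infinity)
recover the 14 classical models exactly, so the methodology interpolates
smoothly among them. Fitting uses a single nested ECM algorithm whose
covariance M-step imposes all three constraints through the weighted
*optimal truncation* operator plus a majorised common-rotation update.
Model choice uses a BIC whose penalty

```
v = kp + (k-1) + [(k-1)(1 - c_det^(-1/p)) + 1]
    + (p-1)(1 - 1/c_shw) [(k-1)(1 - 1/c_shb) + 1]
    + k(rot) p(p-1)/2,       k(rot) = 0 / 1 / k  for I / E / V
```

coincides with the classical free-parameter counts at the limits, searched
in two phases over `k`, the rotation and power-of-two constants.

The package is written tidyverse-style: data frames in, tibbles out,
`tidy()` / `glance()` / `augment()` on every fitted object, `autoplot()`
for clusters, BIC profiles and overlap matrices. It is aimed at
statisticians and applied researchers who cluster moderate-dimensional
continuous data and want explicit control over how different the cluster
covariances may be.

## A worked example

The built-in three-component benchmark draws two informative coordinates
(means `(0,0)`, `(2,6)`, `(6,0)`; covariances `diag(2,2)`, `diag(3,1)`,
`diag(1,2)`; sizes 50/20/20) plus an `N(0, 100)` noise coordinate that
makes unconstrained fits unstable:

```r
library(parsmix)

data <- sim_design_a(seed = 1)
fit <- parsmix(data[1:3], k = 3, c_det = 2, c_shw = 100, c_shb = 2,
               control = parsmix_control(nstart = 50), seed = 1)
fit
#> <parsmix_fit> k = 3, n = 90, p = 3, mode = EM
#> <parsmix_spec> c_det = 2, c_shw = 100, c_shb = 2, rot = V
#>   target loglik = -710.8519, BIC = 1535.876
#>   cluster sizes: 21 49 20
#>   50/50 starts completed, best start converged after 61 iterations

tidy(fit)
#> # A tibble: 3 × 8
#>   component weight  size volume shape_ratio mean_x1 mean_x2 mean_x3
#>       <int>  <dbl> <int>  <dbl>       <dbl>   <dbl>   <dbl>   <dbl>
#> 1         1  0.230    21   6.88        97.4   1.96    6.19    1.64
#> 2         2  0.548    49   5.66        62.9   0.117   0.121  -1.46
#> 3         3  0.222    20   5.46       100.0   5.82   -0.228   0.205

adjusted_rand_index(fit$labels, data$component)
#> [1] 0.964022
```

The recovered means sit at the generating ones, the shape ratios reflect
the dominant noise axis (variance 100 against 1–3), and the partition
agrees with the truth at ARI 0.96 — where an unconstrained VVV fit on the
same data is routinely dragged off by spurious low-variance components.

Model selection over `k` and the constants:

```r
sel <- parsmix_select(data[1:3], k_max = 5, c_levels = 6, seed = 1)
glance(sel)[c("k", "c_det", "c_shw", "c_shb", "rot", "bic")]
autoplot(sel)   # phase-1 BIC profiles, selected model marked
```

A thin command-line interface wraps the same functions
(`inst/cli/parsmix.R`): `simulate`, `fit`, `select` and `score`
subcommands reading/writing CSV and JSON, e.g.

```sh
Rscript inst/cli/parsmix.R simulate --design A --seed 1 --out sim
Rscript inst/cli/parsmix.R fit --input sim_data.csv --k 3 --cdet 2 \
    --cshw inf --cshb 2 --seed 1 --out run
Rscript inst/cli/parsmix.R score --labels-a sim_labels.csv --labels-b run_labels.csv
```

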