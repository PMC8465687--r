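---
title: "Granger causality between time series of graphs: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Granger causality between time series of graphs: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(netgc)
```

## The problem

Two networks evolving in time — say the left and right hemispheres of a
brain, each summarised as a functional connectivity graph per scan volume —
may exchange information directionally. Granger's notion of causality
("a cause cannot occur after its effect"; past values of X improve the
prediction of Y beyond past values of Y alone) is the standard tool for
directed influence between scalar time series, but a graph is not a scalar,
and fitting a VAR to whole adjacency matrices is hopeless at realistic
sample sizes.

`netgc` adopts a latent-parameter view: assume each observed graph is drawn
from some random-graph model whose parameter θ_t is itself a random time
series, and define "graph series 1 Granger-causes graph series 2" as
Granger causality between the latent parameter series Θ₁ and Θ₂. The
parameters are never observed, and for real data the model family is
unknown — so a graph feature that tracks the parameters is needed. The
spectral radius λ₁ (largest adjacency eigenvalue) does this for the
classical families: λ₁ = np for Erdős–Rényi G(n, p); λ₁ = deg exactly for
any deg-regular graph (the all-ones vector is the Perron eigenvector); λ₁
grows with the radius of a geometric graph (dense-regime limit: the
expected degree nπr²) and with the attachment power of a Barabási–Albert
graph; for Watts–Strogatz graphs no analytic form is known, but λ₁ responds
monotonically to the rewiring probability. Inference therefore runs on the
spectral-radius series.

## The VAR model and the two tests

For k series of length T, stacking the feature series into the response
`Y` ((T−p) × k) and the lagged design `Z`, the VAR(p) is `Y = Zβ + u` and
the OLS estimate is `β̂ = (Z′Z)⁻¹Z′Y` — computed by QR decomposition;
`(Z′Z)⁻¹` is materialised only inside the Wald statistic. Residual
covariance: `Σ̂ = û′û / df`.

Non-causality from series i to series j is `a_{i,j}^l = 0` for l = 1…p.
The Wald statistic

W = (Cβ̂_j)′ (C(Z′Z)⁻¹C′)⁻¹ (Cβ̂_j) / Σ̂_{j,j}

is asymptotically χ²_p under the null. Because the restriction involves a
single equation and the statistic is scaled by that equation's residual
variance, for p = 1 it reduces to the squared t-ratio of the cross
coefficient — a useful hand-check that the unit tests exploit.

For short series (fMRI-scale T) the asymptotic reference distribution is
doubtful, and a parametric bootstrap replaces it: fit the VAR; zero the
tested coefficients (all other coefficients, including the intercept, stay
at their unrestricted estimates — re-estimating under the restriction is
deliberately avoided so the null model stays nested in the fit); simulate
bootstrap series by recursing this null model from the first p observed
values, driven by residual **rows** resampled with replacement; refit and
recompute W* per replicate; the p-value is the fraction of W* ≥ W.
Resampling whole rows — all k series at the same time index together — is
essential: the innovations are allowed to be contemporaneously correlated,
and independent per-series resampling would destroy that correlation and
bias the null distribution.

### Numerical and convention choices

* **Intercept.** The equation system includes intercepts v_i, and
  spectral-radius series are far from zero-mean, so the design always
  carries a constant column (appended last; reported separately from the
  lag coefficients). The residual-covariance denominator is accordingly
  `(T−p) − (kp+1)`; `sigma_df = "no_intercept"` restores the `(T−p) − kp`
  denominator that ignores the constant, for comparison with
  implementations that count parameters that way.
* **Coefficient ordering.** One convention everywhere: flat index
  `(i−1)p + l` ⇔ series i, lag l (series-major, lag-minor), for design
  columns, coefficient rows and contrast matrices. The contrast matrix for
  source i is the p rows of the identity at those indices; with an
  intercept the contrast gets an implicit zero column, which is implemented
  as taking the corresponding submatrix of the full `(Z′Z)⁻¹`.
* **Rank handling.** Designs whose smallest singular value falls below
  1e−10 of the largest raise a singular-design error naming the offending
  columns; constant feature series are caught earlier with a clearer
  message. Bootstrap replicates whose refit is singular are discarded with
  a warning and the p-value denominator reduced.
* **Order selection.** AIC over p = 1…p_max, all candidates fitted on the
  common sample aligned at p_max so their likelihoods are comparable:
  `AIC(p) = log det Σ̃(p) + 2pk²/T_eff` with the ML covariance. Ties break
  toward the smaller order. The pipeline caps
  `p_max = min(10, ⌊(T−1)/(k+1)⌋)` to keep the design full rank on short
  series. AIC overfits with positive probability by construction, so tests
  of the selector assert its modal behaviour, not every draw.
* **Bootstrap seeding.** One integer seed; the replicate-by-time index
  matrix is drawn up front, so the whole test is a deterministic function
  of (data, seed) and replicates are independent. `test_all_pairs()`
  derives per-pair seeds as `seed + (i−1)k + (j−1)`.
* **Self-causality** (i = j) is rejected as an error rather than tested:
  only cross-series hypotheses are defined in this framework.

## The simulation framework

The five scenarios are small latent VAR systems with known causal
structure — (1) two independent AR(1) series, the null; (2) a direct
effect y1 → y2; (3) a common driver of two targets; (4) direct and
indirect effects including a lag-2 link; (5) a feedback loop
y2 → y3 → y4 → y2 — with all nonzero coefficients ±0.5 and innovations
drawn jointly normal with unit variances and cross-covariance 0.1. These
values, the inverse-logit normalisation, and the family mappings below
*are* the study conditions, not tuning knobs; the generator defaults
reproduce them exactly.

Latent values map to graph parameters through s = 1/(1+e^(−y)) ∈ (0,1):
ER edge probability p = s; geometric radius r = s; regular degree
deg = ⌊10s⌋; Watts–Strogatz rewiring probability pw = s (with nei = 3 ring
neighbours); Barabási–Albert attachment power ps = 2s (with m1 = 1 edge
per step). Each time point's graph is drawn independently given its
parameter, with per-time-point seeds derived from a base seed.

Decisions where the construction was genuinely open:

* **Initialisation.** The latent recursions start from zeros and discard a
  50-step burn-in, so the retained sample is effectively stationary (all
  scenario systems are stable; the slowest mode has modulus 0.5).
* **Normalisation.** The inverse logit alone maps the series to (0,1); no
  additional min–max rescaling is applied.
* **Degenerate graphs.** ⌊10s⌋ = 0 (latent value below logit(0.1) ≈ −2.2)
  yields an empty regular graph, which violates the framework's
  non-empty-edge-set assumption. The pipeline errors by default;
  `allow_empty = TRUE` substitutes λ₁ = 0 with a warning, and the
  experiment driver uses that path so that rare degenerate draws do not
  abort a Monte-Carlo cell. A regular pair with n·deg odd is repaired by
  decrementing deg with a warning.
* **Experiment order.** `run_experiment()` fits the scenario's true
  maximum lag by default (the application-oriented `order = "auto"` AIC
  path is available); rejection rates are tabulated per directed pair at
  the chosen threshold.

The graph generators: Erdős–Rényi graphs are sampled directly as iid
Bernoulli(p) upper-triangle entries; the geometric (uniform on the unit
square, d = 2), regular (pairing model), Watts–Strogatz (ring lattice plus
per-edge rewiring) and Barabási–Albert (preferential attachment) families
are generated with igraph. One integer seed fully determines a draw.

## Graph features beyond the spectral radius

For the feature comparison, a per-vertex centrality is reduced to one
number per graph by averaging over vertices — the natural graph-level
summary, though not the only one. Betweenness is unnormalised
shortest-path betweenness; closeness is harmonic closeness, finite on
disconnected graphs (ordinary closeness is undefined there); eigenvector
centrality is the mean absolute entry of the unit-norm leading adjacency
eigenvector (equal to 1/√n for any regular graph); degree-mean equals
2m/n. In simulations the spectral radius matches or beats these
alternatives in power, which is why it is the default.

## Time-varying correlation graphs

The front-end for multivariate signals builds one weighted graph per time
point: each channel's smoothing-spline mean is removed; the instantaneous
cross-products of centred signals are spline-smoothed into time-varying
covariances and variances; and the correlation
r_ab(t) = cov_ab(t)/√(var_a(t)·var_b(t)) is clipped to [−1, 1]. One knob —
the spline's equivalent degrees of freedom, default T/10 (at least 4) —
controls the flexibility of means, variances and covariances alike. This
is a convention, not a canonical estimator: the basis, penalty and
per-edge-versus-global smoothing are all choices, and results for this
module are accordingly validated by properties (perfect correlation
recovered, sign changes tracked, small-df limit ≈ static Pearson
correlation) rather than against closed forms. Smoothed squares can
undershoot zero, so variances are floored at 1e−8 and edges touching a
floored variance are set to weight 0 with a warning. For graphs built from
correlations the spectral radius uses the largest eigenvalue (not the
largest absolute value), which is well defined for matrices with negative
entries.

## What the tests do and do not show

The validation suite checks, among others: exact recovery of noiseless
recursions; equality of the OLS solution with an independent pseudo-inverse
computation; the χ²_p null distribution of W (Kolmogorov–Smirnov);
bootstrap p-value uniformity under the null; type-I error at the nominal
level on null graph series; and power that grows with T on the
direct-effect scenario, exceeding 0.8 by T = 100 at n = 300. Problem sizes
in the routine suite are chosen to keep a full run in the tens of minutes
on one core: 400 null replicates (n = 60, T = 100) for the type-I-error
curve, 200 replicates per cell (n = 300, T ∈ {25, 50, 100}) for power, 200
bootstrap-uniformity replicates at 200 bootstraps each; the full published
grid (six graph sizes, four lengths, 1000 replicates, 1000 bootstraps) is
reproducible with `run_experiment()` at its defaults.

All of this validates the method on synthetic graphs whose generating
families are exactly the five above, with independent draws given the
latent parameters. Real dynamic networks — overlapping-window correlation
graphs in particular — have serially dependent estimation noise and need
not resemble any of these families; passing simulations demonstrate
correct test calibration and power under the stated models, not that the
spectral radius captures everything relevant about an arbitrary network's
evolution.

## Known limitations

* Undirected graphs only; a shared vertex count within each series; no
  time-varying vertex sets, multigraphs or self-loops.
* Linear G-causality only (no nonlinear, sparse, structural or
  time-varying VAR variants), and no multiple-testing correction across
  pairs — that is left to the caller.
* The spectral radius is a one-number summary: different parameter changes
  with the same effect on λ₁ are indistinguishable.
* The Barabási–Albert asymptotic spectral-radius report assumes the
  smallest degree equals m1 = 1; it is an order statement, not a
  calibrated value, and is flagged as asymptotic in
  `theoretical_spectral_radius()`.
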