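---
title: "Methods: spatial point-pattern inference for bedding-plane assemblages"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: spatial point-pattern inference for bedding-plane assemblages}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bedplane)
```

## The problem

A mapped bedding plane yields a *marked point pattern*: one planar
coordinate per fossil (taken at the centre of its outline), with taxon,
orientation and size marks, inside an observation window that may contain
holes where the surface could not be read. The scientific questions are
first-order (is the density constant across the surface?) and second-order
(given the density, are specimens independent, or clustered at some
characteristic scale — for example in pairs?). Orientation statistics ask a
taphonomic side-question: were the shells current-aligned, i.e. could
transport rather than behaviour have produced the arrangement?

## Estimators

**Mean intensity.** λ̄ = n/|W|, with |W| the *observable* area (holes
subtracted). Kernel intensity maps use an isotropic Gaussian kernel with
each cell's raw density divided by the kernel mass falling inside the
window, so the map integrates back to n (the tests require 2%). The default
bandwidth is a tenth of the shorter window side — a display default chosen
for map smoothness at the few-metre scale of survey sheets, not an
inferential parameter.

**Ripley's K and L.** The translation-corrected estimator is

K̂(r) = |W| / (n(n−1)) · Σ_{i≠j} 1{d_ij ≤ r} · |W| / |W ∩ W_{x_j−x_i}|.

Two numerical conventions matter:

* *Pair-count denominator.* We divide by n(n−1), not n². Under CSR with a
  Poisson-random count, n(n−1)/|W|² is the unbiased estimator of λ²; with
  n² the estimate of K carries a downward ratio bias of order 1/n, which
  propagates into a roughly 10% upward bias of the cluster-model parent
  intensity recovered by minimum contrast at the n ≈ 70 of a realistic
  sheet. The tests confirm unbiasedness (mean K̂ within 3 Monte-Carlo
  standard errors of πr² over 200 CSR simulations).
* *Closed balls.* Ties d_ij = r count as ≤ r, so the estimator is a right-
  continuous step function and results are deterministic under coordinate
  rounding.

The default distance grid is 513 values from 0 to a quarter of the shorter
window side — the conventional rule; estimates beyond half the window side
are unreliable and warned about. L̂ = √(K̂/π) is used for display and
testing because its CSR reference is the straight line L = r and its
variance is approximately stabilised in r.

**Pair correlation function.** Epanechnikov kernel, "divisor d" variant
(the pair distance, not the argument r, appears in the denominator), which
reduces the small-r bias of the classical estimator. Default half-width
0.15/√λ̄ (Stoyan's rule). Values at r below one bandwidth remain
boundary-affected and are flagged rather than silently trusted.

**Edge correction.** Translation correction throughout. The set covariance
|W ∩ W_s| is closed-form for rectangles. For polygonal windows with holes
it is computed on a raster: a single call rasterises at 1024² by default,
while the per-pair weights inside K/g use an FFT autocorrelation of a 256²
window mask, interpolated bilinearly at each pair displacement — the same
approximation at O(1) cost per pair after one transform, verified against
direct rasterisation and a Monte-Carlo overlap oracle to within 1%. The
interpolated covariance is clipped below at one pixel area so weights stay
finite for pathological displacements.

## Models and fitting

**Homogeneous Poisson (CSR).** The null model; its one parameter is λ̄
itself.

**Inhomogeneous Poisson.** Intensity log-linear in the Cartesian
coordinates, λ(x,y) = exp(β₀+β₁x+β₂y) — a deliberately weak trend model
for surfaces without covariates. Fitting uses the Berman–Turner device: a
32×32 dummy grid plus the data points, counting weights from per-tile
observable area (tile areas measured on the window raster so holes are
respected), and a weighted Poisson GLM. The score equation makes the
fitted intensity integrate to n over the quadrature scheme; the tests
check the integral to 1%. Simulation is by thinning a dominating
homogeneous process, whose maximum over the window sits at a bounding-box
corner for a log-linear intensity.

**Thomas cluster process.** Poisson parents (intensity κ), Poisson(μ)
offspring per parent, isotropic Gaussian dispersal (sd σ), theoretical
K(r) = πr² + (1/κ)(1 − exp(−r²/4σ²)). Fitted by minimum contrast with the
conventional exponents: minimise ∫₀^rmax (K̂^{1/4} − K_θ^{1/4})² dr on the
summary grid (trapezoid rule), Nelder-Mead on (log κ, log σ), and recover
μ from the intensity identity μ = λ̄/κ̂. Starting values κ₀ = λ̄/2,
σ₀ = 0.1·rmax.

**Pair process (modified Gauss–Poisson).** Poisson parents; each parent is
replaced by *two* points placed independently and uniformly in the disc of
radius r_c around it, one of which is deleted with probability 1−P. This
is the "preferential pairing" alternative to the Thomas model's
Poisson-sized clusters. Its theoretical K is unknown, so the model curve
at each candidate (r_c, P) is estimated from 100 simulated patterns.
Four stabilising choices:

* *Common random numbers.* One fixed pool of simulation seeds is reused at
  every objective evaluation, making the objective a deterministic
  function of the parameters; without this, Nelder-Mead chases Monte-Carlo
  noise and the "fit" depends on the simplex trajectory. Two fits with the
  same seed are bit-identical (a tested contract).
* *Intensity constraint.* κ is eliminated via λ̄ = κ(1+P), leaving two free
  parameters optimised as (log r_c, logit P). Fitting κ freely against a
  simulated, noisy objective is poorly identified at n ≈ 70; the
  constraint pins the one combination the data determine well.
* *Centred contrast.* The objective matches K̂_obs^{1/4} against the
  pointwise mean of the *fourth roots* of the simulated Ks, not the fourth
  root of their mean. The transform is concave, and the observed curve is
  a single noisy draw: matching it to a transform of a smooth average
  systematically prefers weaker clustering (in calibration experiments
  here, a downward shift of ~0.2 in the recovered P). With both sides the
  same functional of the same estimator, observed and simulated curves are
  exchangeable at the true parameters and the contrast is centred.
* *Grid pre-search.* The K excess identifies P only through the weak
  factor 2P/(1+P), so the objective is nearly flat in P, and it is
  piecewise-steppy because simulated counts are discrete. Nelder-Mead from
  a single start point stalls wherever it begins (calibration: fits
  started at P₀ = 0.5 ended near 0.55, fits started at 0.9 ended near
  0.93). The optimiser therefore scans a deterministic 6 × 9 grid in
  (log r_c, logit P) and polishes the best node; with this, the recovered
  P is approximately median-unbiased and its remaining spread is genuine
  sampling uncertainty. A fitted P within 0.01 of either boundary is
  flagged (`boundary`), and a fit whose optimum improves on the degenerate
  no-pairing model (P ≈ 0) by less than a factor of two is flagged
  `no_signal` — on CSR input the pair signal is absent and the fitted
  parameters are not interpretable.

Cluster simulations draw parents on the bounding box dilated by a buffer
(4σ, or r_c) so clusters straddling the edge contribute; a Poisson process
restricted to any superset of the dilated window is again Poisson, so
sampling parents on the enlarged rectangle is exact, and a test verifies
the expected count is invariant to doubling the buffer. Simulated counts
are Poisson — we do not condition on the observed n.

## Monte-Carlo inference

**Envelopes** are the pointwise min/mean/max of n_sim = 99 simulated
summary curves. They are a diagnostic display, *not* a calibrated
simultaneous test: measured over repeated CSR experiments here, the full
observed curve stays inside the 99-simulation band only ~85% of the time
(curves are smooth, so the band is breached whenever the observed curve is
the pointwise extreme anywhere along the grid). The regression test
therefore asserts a 75% floor — enough to catch a broken envelope — and
inference is delegated to the DCLF test.

**DCLF test.** Each curve i (observed and simulated alike) gets
u_i = Σ_k (H_i(r_k) − H̄_{(−i)}(r_k))² Δr with H̄_{(−i)} the mean of the
*other* curves, so the observed pattern is treated symmetrically; then
p = (1 + #{u_sim ≥ u_obs}) / (n_sim + 1). Ties count toward rejection
(conservative); the smallest attainable p with 99 simulations is 0.01;
with n_sim = 1 and a perfectly reproduced curve the rank convention yields
p = 1. The default statistic is L over the full default grid (the test is
configurable to K or g and to a restricted r range). Model envelopes and
tests simulate from the *fitted* model without per-simulation refitting;
the refitting ("balanced") variant is out of scope. Under the null the
p-value is uniform on its attainable grid (tested: Kolmogorov distance
< 0.1 over 500 runs) and the size at α = 0.05 is inside the exact binomial
interval over 200 runs.

## Circular statistics

R̄ and θ̄ come from the resultant of unit vectors; the angular standard
deviation is the *circular* standard deviation v = √(−2 ln R̄) (in
degrees). The competing convention √(2(1−R̄)) (angular deviation) differs
materially at small R̄: at R̄ = 0.18, √(−2 ln R̄) gives 106°, which is the
definition consistent with the published headline pair (R̄ = 0.18,
v = 106°), and is the one implemented. Kuiper's V = D⁺ + D⁻ is computed
against the uniform circular CDF, modified as
V* = V(√n + 0.155 + 0.24/√n), with the tail series
p = Σ_m 2(4m²V*²−1)exp(−2m²V*²) truncated at 1e−10 or 100 terms. Exact
small-n tables are not used; the corrected asymptotic p is adequate for
n ≥ ~10 and the tests confirm correct size at n = 73. All angles are
degrees counterclockwise from +x in the adoral direction; statistics are
rotation-invariant (tested), so the axis convention affects only reported
mean directions.

## The synthetic scene generator

The generator states a world resembling the motivating survey and holds it
fixed:

* 8 × 10 m rectangle (80 m²); oncocerid layer from the pair process with
  expected count 73 before gap thinning, r_c = 0.28 m, P = 0.75;
  ammonoid layer homogeneous Poisson at 3.42/m² (optionally log-linear);
  orthocerid layer at 1.0/m².
* Gaps: random disjoint discs (24-gons) removed until 9% ± 1 point of the
  area is masked. Gaps *thin* points rather than displace them — a fossil
  under cover is unobservable, not moved — so layers are simulated
  directly on the holed window.
* Marks: orientations uniform by default (von Mises optional); widths
  truncated-Normal(55, 12) mm — symmetric, as observed; lengths
  Gamma(shape 3, scale 31.3) mm, giving mean ≈ 94 mm and median ≈ 84 mm —
  the right-skew that random erosional sectioning of a conical shell
  produces. The skew is modelled phenomenologically; no 3-D shell geometry
  is attempted. Pair members are drawn independently (no within-pair size
  correlation by default, there being no published estimate of it).

What a green end-to-end test establishes: on data *generated by these
models*, the pipeline rejects CSR for the paired layer, retains the
cluster models for it, and retains CSR for the random layer, in ≥ 80% of
seeds. What it does not establish: anything about measurement error,
time-averaging, taphonomic transport, or real gap geometry — the real
study's gap polygons were never published, so gap handling is validated
only against synthetic masks of the same total area.

## Numerical choices and degenerate inputs

* Boundary convention: points on the outer boundary are inside, points on
  a hole boundary are outside; containment is deterministic, so repeated
  reads of the same CSV validate identically.
* Self-intersecting rings are rejected with an invalid-geometry error;
  either winding order is accepted and normalised on GeoJSON read.
* Duplicate coordinates warn (outline centres can collide after rounding)
  but are kept; K and g are well-defined with zero-distance pairs only
  through the divisor-d guard, which clips pair distances at machine
  epsilon.
* Patterns with n < 2 cannot produce summary functions; simulations that
  land there inside envelopes/tests are resampled with a shifted seed, up
  to a retry cap, and logged.
* Fits with fewer than 10 points are refused; the pipeline emits such rows
  with statistics suppressed and a note instead of failing the whole
  table.
* All seeds are explicit arguments, echoed into results; every stochastic
  experiment in the tests fixes them.

## Known limitations

* Raster set covariance limits edge-correction accuracy on heavily holed
  windows to ~1%; exact polygon Minkowski algebra is deliberately out of
  scope.
* The inhomogeneous model is restricted to log-linear trends in x and y;
  using the data's own smoothed intensity as the trend (sometimes done
  elsewhere) risks overfitting and is not offered.
* Envelope bands are pointwise; global/rank envelopes and the MAD test are
  not implemented.
* The pair-process fit inherits Monte-Carlo roughness from its simulated
  objective; with common random numbers it is deterministic but its
  objective surface is still a step-like approximation, so the reported
  optimum is accurate only to the scale of that roughness (the recovery
  test bounds the median error in P at 0.15).
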