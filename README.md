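# bedplane

Spatial point-pattern inference for fossil assemblages mapped on bedding
planes.

Palaeoecologists increasingly read behaviour out of *where* fossils lie:
whether specimens on an exposed sediment surface are randomly scattered,
follow a density gradient, or cluster — and at what scale. A concrete
motivating case is a Middle Devonian surface carrying dozens of breviconic
cephalopods that appear to lie preferentially in *pairs*, a pattern with
direct bearing on whether the animals died together (e.g. after mating,
suggesting a semelparous life cycle), while ammonoids on the same surface
look spatially random. `bedplane` packages the full inferential chain such a
study needs:

* **Observation windows with gaps** — polygonal survey sheets minus patches
  where observation was impossible (sand, calcrete, vegetation), stored as
  GeoJSON polygons with holes.
* **First-order structure** — mean intensity λ̄ = n/|W| and kernel-smoothed,
  edge-corrected intensity maps.
* **Second-order structure** — Ripley's K, the variance-stabilised
  L-statistic L(r) = √(K(r)/π), and the pair correlation function g(r)
  (Epanechnikov kernel, divisor-d), all with the translation edge
  correction e_ij = |W| / |W ∩ W_(xj−xi)|.
* **Point-process models** — homogeneous Poisson (CSR), log-linear
  inhomogeneous Poisson λ(x,y) = exp(β₀+β₁x+β₂y) fitted by the
  Berman–Turner quadrature device, the Thomas cluster process fitted by
  minimum contrast against its closed-form
  K(r) = πr² + (1/κ)(1 − e^(−r²/4σ²)), and a modified **Gauss–Poisson pair
  process** (parents get exactly two points uniform in a disc of radius
  r_c, one deleted with probability 1−P) fitted by *simulation-based*
  minimum contrast with common random numbers, since its theoretical K is
  unknown.
* **Monte-Carlo inference** — pointwise simulation envelopes and the
  Diggle–Cressie–Loosmore–Ford (DCLF) test,
  p = (1 + #{u_sim ≥ u_obs}) / (n_sim + 1).
* **Circular statistics** — mean resultant length R̄, mean direction θ̄,
  angular standard deviation v = √(−2 ln R̄), and the modified Kuiper test
  of uniformity for shell orientations (current-alignment check).
* **Synthetic scenes** — a generator producing bedding-plane data with all
  of the above structure, so the entire pipeline is testable end to end
  without any field data.

## Worked example

```r
library(bedplane)

# a synthetic 8 x 10 m surface: pair-clustered oncocerids (target n = 73,
# pair radius 0.28 m, retention P = 0.75), random ammonoids (3.42 / m^2),
# 9% of the surface masked by gaps
scene <- generate_scene(scene_config(seed = 42))
onc <- subset_taxon(scene$pattern, "Oncocerida")
onc
#> point pattern: 67 points, mean intensity 0.92 / m^2
#> window (polygon): [0, 8] x [0, 10] m, 12 hole(s), area 72.85 m^2
#> marks: taxon, angle_deg, length_mm, width_mm

# does the oncocerid layer deviate from complete spatial randomness?
dclf_test(onc, fit_hom_poisson(onc), n_sim = 99, seed = 1)
#> DCLF test (L, 99 sims, model hom_poisson): u = 0.125, p = 0.01

# fit a Thomas cluster model by minimum contrast ...
tc <- fit_thomas_mincontrast(onc)
tc$spec
#> thomas: kappa = 0.6102, sigma = 0.1764, mu = 1.507

# ... and the pair process by simulation-based minimum contrast
gp <- fit_pair_mincontrast(onc, m_sims = 100, seed = 2)
gp$spec
#> pair_process: kappa = 0.4779, r_c = 0.2497, p_ret = 0.9245

# the spatially random ammonoid layer, by contrast, keeps CSR standing
amm <- subset_taxon(scene$pattern, "Ammonoidea")
dclf_test(amm, fit_hom_poisson(amm), n_sim = 99, seed = 3)
#> DCLF test (L, 99 sims, model hom_poisson): u = 0.0002757, p = 0.77
```

The DCLF p of 0.01 (the smallest value attainable with 99 simulations)
rejects CSR for the clustered layer, while the cluster fits land in the
generating neighbourhood (this scene was generated with r_c = 0.28 m,
P = 0.75; single-pattern cluster fits at n = 67 are noisy, which is why
the recovery tests quote *median* errors over replicates). The ammonoid
layer stays comfortably inside CSR.

A minimal command-line entry point is installed at `inst/cli/bedplane`
(subcommands `simulate`, `summary`, `gof`, `table1`, flags `--seed`,
`--nsim`, `--out`).

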