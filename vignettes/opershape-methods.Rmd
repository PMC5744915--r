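---
title: "Models, conventions and numerical choices in opershape"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models, conventions and numerical choices in opershape}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(opershape)
```

opershape analyses the macroevolution of 2-D landmark shapes — its template
case is the teleost opercle, a flat gill-cover bone digitised as 4 fixed
landmarks and 14 edge semilandmarks — on a time-calibrated phylogeny. This
vignette is the package's own account of the models it fits, the
conventions it fixes where the field leaves choices open, and the numerical
decisions a user or reviewer may want to audit. Everything quantitative
stated here is computed by the test suite or the acceptance script; nothing
is quoted from external analyses.

## Superimposition

`gpa()` performs full generalized Procrustes analysis: translation to the
centroid, scaling to unit centroid size, and iterative rotation to the
consensus via the cross-covariance SVD, with the consensus re-centred and
re-scaled each round. Iteration stops when the root-mean-square consensus
displacement falls below `tol` (default 1e-10) or after `maxIter = 100`
rounds; the result records both. Two conventions matter:

* **Semilandmarks are not slid.** Edge points are placed at constant
  intervals along outline segments and treated as fixed landmarks. Sliding
  by bending-energy or Procrustes-distance minimisation is a deliberate
  non-goal; for edge points spaced as densely as the 18-point scheme, the
  difference is far smaller than between-family shape differences.
* **No tangent-space projection.** Analyses use the aligned coordinates
  directly, in MorphoJ style. At the Procrustes distances a single bone
  spans (well under 0.3 in our synthetic and template configurations) the
  tangent approximation error is quadratically small and does not change
  any test decision.

Left-side configurations (`side == "left"`) are mirrored onto the right
before fitting, after which reflections are disallowed unless
`allowReflection = TRUE`. Reflection of a body side is a labelling
artefact, not shape variation, and mirroring leaves all pairwise Procrustes
distances unchanged (asserted in the tests).

Replicate specimens of one taxon are averaged coordinate-wise *after* joint
superimposition (`averageByTaxon()`), then the taxon-level means are
superimposed again. Choosing which species exemplifies a family is the
caller's responsibility via the input table; the pipeline only averages
specimens sharing a taxon label. Note that TPS records carry no taxon
field — `readTPS()` uses the record ID as the taxon — so multi-specimen
averaging needs the CSV format (or an in-memory `LandmarkSet`) where taxon
is explicit.

## Morphospace and density landscape

`shapePCA()` is covariance (not correlation) PCA of the flattened aligned
coordinates: Procrustes coordinates are in common units, so correlation
scaling would distort the metric. Axis polarity is arbitrary in any PCA; we
orient every eigenvector so its largest-magnitude loading is positive,
which makes scores reproducible across runs and platforms. Published plots
of the same data may be flipped relative to ours.

`kdeLandscape()` estimates occupancy with a product-Gaussian kernel on a
`200 x 200` grid spanning the scores plus three bandwidths (so the density
integrates to 1 within 2%); the default per-axis bandwidth is Silverman's
rule, `0.9 min(sd, IQR/1.34) n^{-1/5}`. The original analyses used an
interactive statistics package whose contouring rule is not documented; as
a stated stand-in, contour levels sit at the 10 deciles of the density
evaluated at the data points, so the highest contour encloses roughly the
densest tenth of the sample. Exact peak boundaries are therefore *inputs*,
not outputs: focal regions are user-supplied ellipses
(`focalRegion(center, semiAxes, angle)`), boundary-inclusive.

## Phylomorphospace and ancestral states

`ancestralSCP()` minimises the branch-length-weighted sum of squared
changes, `sum(Δz² / v)` over edges — the Brownian-consistent variant, whose
solution equals the ML/GLS ancestral states (the tests cross-check against
an independent implementation). The unweighted variant (`weighted = FALSE`)
is provided because some classic phylomorphospace software used it; the
weighted form is the default. The minimiser is linear in tip values, so
`scpOperator()` exposes the mapping matrix for repeated evaluation on
simulated data. Zero-length branches are replaced by `1e-8 x tree depth`
with a warning; polytomies are accepted as-is. Ancestors for the
phylomorphospace (and the convergence metrics) are computed on the PC1–PC2
scores, matching how such plots are drawn, not on the raw coordinates.

## Phylogenetic signal, disparity and rates

`kmult()` implements the multivariate K: the ratio of the mean-centred to
phylogenetically whitened generalized sums of squares (centred at the GLS
root, whitened by the inverse square root of the tree covariance), divided
by its Brownian expectation `(tr(C) − n/sum(C⁻¹)) / (n − 1)`. For one trait
it reduces exactly to Blomberg's K (asserted to 1e-8 against a directly
coded oracle and an independent package). Significance permutes taxa across
tips; the default 10,000 permutations give p-resolution of 1e-4; the
`(count + 1)/(N + 1)` estimator keeps p in (0, 1].

`procrustesVariance()` is the mean squared distance of group members from
the group mean (divisor *n*). For two members symmetric about their mean
with residual norm `e` it equals `e²` — equivalently `d²/4` for two shapes
separated by `d` — and in general equals the double-loop identity
`(1/2n²) ΣΣ d_ij²`; both are asserted. `disparityTest()` permutes group
labels and uses the absolute pairwise variance difference as the statistic
(the convention of the standard disparity tool), not the ratio; the
reported fold difference is max/min.

`compareEvolutionaryRates()` estimates per-group `σ²_mult` as the mean
squared phylogenetically whitened residual per trait dimension and tests
the max/min ratio against datasets simulated under the pooled common rate
on the same tree — the simulation-based test; a permutation alternative is
not implemented. Type-I error of both tests is checked to lie in
[0.02, 0.08] at the 5% level under null simulations.

## Evolutionary model selection

`fitEvolutionaryModels()` fits four single-trait models by ML under a
multivariate-normal tip likelihood, with the rate and root concentrated out
(profile likelihood), leaving at most a 1-D optimisation:

| model | tip covariance (unit rate) | free parameters (k) |
|-------|----------------------------|---------------------|
| BM | shared path depths `C` | σ², z0 (2) |
| WN | identity | σ², mean (2) |
| OU | `(1 − e^{−2αC}) e^{−αd} / (2α)` | σ², α, z0 (3) |
| EB | `(e^{rC} − 1)/r`, r ≤ 0 | σ², r, z0 (3) |

OU uses the fixed-root (non-stationary) convention on an ultrametric tree,
under which the optimum θ equals the root state z0 — both are reported but
k counts 3. α is optimised in `[1e-8, 50]/depth` and r in `[−10, 0]/depth`
(`stats::optimize`, tolerance 1e-10); these bounds are package choices, not
published values. The EB fit explicitly compares its interior optimum with
the r = 0 boundary and returns the BM-equivalent fit when the boundary
wins, which makes the BM-nesting identity exact. AICc is
`−2lnL + 2k + 2k(k+1)/(n−k−1)` and dAICc is measured from the best model;
below 2 is conventionally read as support. Model fitting in the pipeline
runs on PC1 and PC2 separately — individual PCs, not a joint fit — because
that is the contrast the comparison table is designed for; multivariate and
multi-regime variants are out of scope.

There is no standard formula for a dAICc standard error; an optional
parametric bootstrap (`bootstrapSE = n` re-simulates from the best model
and refits) provides one behind a flag, off by default.

## Convergence metrics

`cSimilarity()` computes, per focal pair, `Dtip` (tip distance in the PC
plane) and `Dmax` (the maximum distance between any two states — tips or
reconstructed ancestors, one from each lineage traced back to the common
ancestor; states at tree nodes only, no interpolation along edges). Then
`C1 = 1 − Dtip/Dmax`, `C2 = Dmax − Dtip`, `C3 = C2 / (evolution summed
along both lineages)`, `C4 = C2 / (evolution summed over the clade below
the common ancestor)`. Multi-taxon focal sets aggregate pairwise values by
the mean (configurable to min/max). `c5Count()` counts edges whose parent
point lies outside a region and whose child lies inside; an edge passing
fully through the region is *not* counted, a known limitation on coarse
trees, and a "lineages" variant that collapses entries leaving no tip
inside the region is also available.

`convergenceTest()` simulates the null by Brownian motion at the per-axis
ML rate of the observed scores (zero trait correlation — the simulation
covariance is not published, so independence is the stated choice), rooted
at the GLS estimate so that region-based C5 tests are evaluated against the
fixed region in the right part of the plane. Convergence p-values use the
bare `count / nSims` convention — deliberately different from the
`(count+1)/(N+1)` rule used elsewhere in the package — so that an empirical
metric exceeding every simulation reports p = 0, the convention of the
published convergence tables.

## The synthetic-data generator

`simulateShapeDataset()` produces datasets with the statistical structure
the analyses assume, and is itself tested:

* **Tree.** Pure-birth (Yule) from two crown lineages, stopping when the
  n-th lineage appears plus one further full exponential epoch, so the
  expected crown depth is `sum(1/(λ j)), j = 2..n` (checked against that
  formula over 500 trees). This simple stop-at-n scheme has a slight
  conditioning bias relative to generalized sampling approaches; for
  fixtures that bias is irrelevant and it keeps depths analytically
  checkable.
* **Shapes.** A fixed 18-point template on a smooth convex fan (a perturbed
  polar curve, hence simple by construction), deformed along orthonormal
  low-order trigonometric edge-displacement fields. Orthonormality makes
  latent traits map near-linearly onto Procrustes/PC space, so
  parameter-recovery tests have analysable ground truth. Latent traits
  evolve by BM, single-optimum OU, or OU with regime painting
  (`OU_convergent`): an edge is in a regime when every tip below it belongs
  to the regime's taxon set, i.e. designated clades including their stems.
* **Defaults as study conditions.** 100 taxa; birth rate 0.0167/My (expected
  crown depth ≈ 250 My, the scale of a teleost family-level tree); 2
  deformation axes (mirroring analyses that live in the PC1–PC2 plane);
  trait variance 1e-4/My per axis, giving tip deformation SD ≈ 0.16 on a
  unit-centroid-size template — prominent but far from degenerate shape
  variation; replicate landmark noise SD 0.005 (landmark digitisation error
  two orders below shape differences); one replicate per species unless
  asked otherwise.
* **Convergent scenarios.** The power checks use two *distant* clades —
  the disjoint pair whose ancestors are maximally separated on the tree —
  driven to one shared optimum, with attraction `α = 50/depth`. The
  strength is chosen so clades equilibrate at the optimum regardless of
  clade age: at weaker pull (α·depth near the 2–16 range) a clade that
  originated recently travels only partway to the optimum, which is
  genuinely ambiguous convergence rather than the unambiguous ground truth
  a power test should encode.
* **Outlines.** `simulateOutlines()` interpolates the deformed template's
  edge points with a periodic spline into closed 400-point curves,
  rejecting self-intersections (traits shrunk toward zero on repeated
  failure) — fixtures for the elliptical-Fourier cross-check.

What the generator does **not** emulate: real opercle anatomy (spines,
struts, regional edge elaborations), digitisation bias that correlates
across landmarks, non-ultrametric trees, fossil sampling, or
model-misspecified shape evolution (e.g. punctuated change). Passing tests
therefore demonstrate correctness of the machinery and calibration under
the stated models — not that real opercle data satisfy those models.

## Elliptical-Fourier conventions

`efa()` computes Kuhl–Giardina coefficients of the closed polyline. The
traversal parameter advances **uniformly per point** by default; after
`resampleOutline()` (equal arc-length spacing) this equals arc-length
parameterisation, and a uniformly sampled ellipse reduces exactly to its
first harmonic — the property the tests pin down. Under pure chord-length
parameterisation that identity is genuinely false for non-circular
ellipses (the coordinate functions of an ellipse are not single harmonics
in arc length), which is why `parameter = "arc"` exists only as an option
for un-resampled outlines. Normalization follows the first-harmonic
convention: rotate the phase so the start lies on the first ellipse's
semi-major axis, rotate the coefficient pairs so that axis lies along x,
divide by the semi-major magnitude (size removal), and fix traversal
direction by requiring d1 ≥ 0; the canonical first harmonic is then
(1, 0, 0, d1). The harmonic count H counts all harmonics including the
first, default 30, and must satisfy H ≤ q/2 (aliasing). Reconstruction
error falls monotonically with H until it reaches the piecewise-linear
discretisation floor, where it may jitter at the 1e-8 level — the tests
assert monotonicity with exactly that allowance. The concordance between
landmark and outline morphospaces is delivered as a rank correlation of
inter-taxon distance matrices (a report, not a sharp contract), because the
underlying claim — that the two representations place taxa in approximately
the same regions — is qualitative.

## Pipeline, seeds and p-value conventions

`runFullAnalysis()` executes averaging → GPA → PCA → landscape →
phylomorphospace → signal → disparity → rates → models (PC1, PC2) →
convergence per region. Taxa missing from the tree are dropped with a
recorded list; fewer than 4 survivors aborts. Every stochastic stage
receives a sub-seed derived deterministically from the master seed, so a
report is byte-identical across reruns and each statistic equals the
corresponding module function called directly with that sub-seed (both
asserted). Permutation/simulation p-values use `(count+1)/(N+1)` except
the convergence module's bare-count convention, documented above.

## Problem sizes used by the tests

The calibration suite runs at: Kmult — 500 Brownian replicates and 500
no-signal replicates (199 permutations each) on a fixed 64-tip tree;
disparity and rate tests — 200 null replicates each (99
permutations/simulations) plus 200 replicates of a 4x clade-rate contrast;
model selection — 200 OU-generated datasets (α·depth = 3) on a 128-tip
tree; convergence — 100 null and 100 convergent-regime replicates (199
simulations each) on 32-tip trees. These sizes keep the full suite around
two to three minutes on one core while leaving the binomial noise on every
calibration band well inside the asserted interval.

## Known limitations

* No sliding semilandmarks and no 3-D support, by design.
* C5 misses transits that enter and leave a region within one edge.
* Ancestral-state uncertainty is not propagated into the C metrics; the
  phylomorphospace is a point reconstruction.
* OU fitting assumes an ultrametric tree and a single regime; EB and OU
  cannot be distinguished from BM on star-like trees (they collapse to the
  same covariance), which the AICc penalty then adjudicates.
* The TPS reader applies SCALE factors but the pipeline's Procrustes
  scaling removes size anyway; centroid sizes are retained only as
  metadata.
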