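---
title: "Methods: presence-background niche modelling and reserve planning with sdmplanr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: presence-background niche modelling and reserve planning with sdmplanr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

sdmplanr implements a complete species-distribution-modelling and
systematic-conservation-planning workflow on geographic raster grids: a
presence-background maximum-entropy habitat model with grid-based tuning,
habitat classification and range-change analysis, simulated-annealing
reserve selection, and protected-area gap analysis. A synthetic landscape
generator supplies inputs with known structure, so the whole chain is
testable offline and parameter recovery can be verified against ground
truth. This vignette is the package's account of the underlying methods,
the defaults, and the design decisions taken where conventions genuinely
differ between implementations.

## The maximum-entropy model

Given presence locations $x_1,\dots,x_m$ and a background sample of
landscape cells, the model is the Gibbs distribution over background cells

$$q_\lambda(x) = \frac{e^{\lambda \cdot f(x)}}{Z_\lambda},\qquad
Z_\lambda = \sum_{b} e^{\lambda \cdot f(b)},$$

whose coefficients maximize the L1-penalized presence log-likelihood

$$\frac1m \sum_i \lambda \cdot f(x_i) \;-\; \log Z_\lambda \;-\;
\sum_j \beta_j |\lambda_j|.$$

**Features.** `buildFeatures()` expands each predictor into the standard
classes — linear (L), quadratic (Q), pairwise product (P), forward hinge
(H) and threshold (T) — all min–max scaled to $[0,1]$ over the pooled
presence-plus-background sample. Hinge and threshold features use 30
evenly spaced interior knots per variable. Forward hinges only: together
with the linear feature they span descending responses adequately at this
scale, and halving the hinge count keeps the design small. Constant
variables contribute no Q/H/T features (with a warning). At prediction
time inputs beyond the training range are clamped to the scaling bounds.

**Regularization.** The per-feature penalty is
$\beta_j = \mathrm{RM}\times \beta_{\mathrm{class}}(m)\times
\max(s_j, 0.05)/\sqrt{m}$, where $\beta_{\mathrm{class}}(m)$ is the
published per-class default schedule interpolated on the presence count
(linear/quadratic/product: 1.0 at $m \le 10$ down to 0.05 at $m \ge 100$;
hinge: 0.5; threshold: 2.0 down to 1.0), $s_j$ is the feature's standard
deviation over the presences, and RM is the user-facing regularization
multiplier. The $s_j/\sqrt m$ factor is part of the reference schedule;
without it the bare class constants would over-penalize $[0,1]$-scaled
features at realistic presence counts. The sd floor of 0.05 prevents
near-constant hinge features from escaping regularization.

**Optimizer.** Cyclic coordinate descent with closed-form soft-threshold
updates on a local quadratic bound: for feature $j$ with gradient
$g_j = \bar f_j^{\mathrm{pres}} - E_q[f_j]$ and curvature
$h_j = \mathrm{Var}_q(f_j)$ (floored at $10^{-6}$), the update is the
soft-thresholded Newton step $S(\lambda_j + g_j/h_j,\ \beta_j/h_j)$. A
candidate step whose exactly-evaluated objective change is negative (the
bound can fail for large steps) is skipped. Convergence is declared when a
full cycle improves the objective by less than $10^{-6}$; after 500
cycles the best iterate is returned flagged non-converged. Every accepted
update's objective increment is recorded and credited to the underlying
variable, which is what `percentContribution()` later normalizes to 100%.

**Normalization and output.** By default the presences are appended to the
background for normalization (target-group union), matching reference
behaviour; `addPresences = FALSE` disables it. The logistic output is
$p = e^{H} q/(1 + e^{H} q)$ with $H$ the entropy of the fitted background
distribution — the classic logistic transform with prevalence parameter
0.5, chosen (rather than cloglog) because the workflow this package
reproduces uses logistic-format grids. A null model therefore scores
exactly 0.5 everywhere, which the tests assert.

**Replicates.** `runReplicates()` implements the usual protocol: 25% of
presences held out per replicate, training presences drawn by bootstrap
from the remaining 75%, ten replicates by default, and the mean logistic
raster across replicates as the working suitability surface.

## Tuning

`candidateGrid()` crosses RM $\in \{0.5, 1.0, \dots, 4.0\}$ with the six
feature combinations L, LQ, H, LQH, LQHP, LQHPT — 48 candidates.
Selection is by small-sample AICc: raw scores standardized to sum 1 over
all land cells, $\ln L$ summed at the presences, $k$ the count of
coefficients with $|\lambda_j| > 10^{-8}$, and
$\mathrm{AICc} = 2k - 2\ln L + 2k(k+1)/(n-k-1)$, flagged invalid when
$k \ge n-1$. Two conventions are unstated in the ecology literature and
fixed here explicitly: AICc models are fitted on the **full** presence set
(no split), while `avg.diff.AUC` comes from the bootstrap replicate
scheme; and delta-AICc ties are broken toward smaller RM, then fewer
feature classes (prefer the simpler model, deterministically).

## Habitat classification and range dynamics

Suitability surfaces are classified with fixed breaks 0.1 / 0.24 / 0.5
into unsuitable, slightly, moderately and optimally suitable habitat.
Intervals are left-closed, $[b_k, b_{k+1})$, with the top interval closed
at 1 — the printed "0~0.1" style of class table does not specify closure,
so the convention is documented and tested. An exact Fisher–Jenks routine
(`jenksBreaks()`, dynamic programming) is available for data-driven
breaks. Binary maps use the *maximum training sensitivity plus
specificity* threshold (`mtssThreshold()`, an exact scan over the distinct
observed scores) and strict `>`, following the usual "higher than the
threshold" phrasing; cells exactly at the threshold are the documented
one-cell difference between `classifySuitability()` (where 0.24 is
moderately suitable) and `binarize()` (where 0.24 is unsuitable), and the
tests count them.

Areas are spherical: a cell in row $r$ has area
$R^2\,\Delta\lambda\,(\sin\phi_t - \sin\phi_b)$ with $R = 6371.0088$ km,
so class areas, change-map categories (gain / loss / stable) and
centroids are all area-weighted. Range centroids weight suitable cells by
area (mass = area; suitability weighting is available by flag), and
centroid shifts use the WGS84 geodesic via geosphere, with great-circle
haversine as a cross-check that agrees within 0.5%.

## Reserve selection

`buildPlanningUnits()` aggregates the binary suitability map into
planning units of nominally 10 km, with the conservation-feature amount
equal to the suitable-habitat area inside each unit and shared boundary
lengths along block interfaces. Cost defaults to unit land area, the
standard planning convention; `costMode = "habitat"` instead uses the
suitable-habitat content as the cost, reproducing the unconventional
cost definition some workflows state (it penalizes selecting suitable
cells). The objective is

$$\sum_{\mathrm{selected}} \mathrm{cost}
 + \mathrm{BLM}\times(\text{exposed boundary})
 + \mathrm{SPF}\times\frac{\text{shortfall}}{\text{target}}\times
   C_{\mathrm{greedy}},$$

where the exposed boundary counts edges shared with unselected units and
exterior edges (4-neighbour adjacency), and $C_{\mathrm{greedy}}$ is the
cost of a greedy target-completing set — the documented shortfall-
proportional penalty form. Annealing starts from a random selection,
flips one unit per step, and cools geometrically from an initial
temperature set to the mean $|\Delta|$ of 100 random probe flips down to
$10^{-4}$ of it. The published workflow's "iterations = 50" is read as 50
repeat runs (50 single flips would be meaningless); flips per run default
to $10^6$. On instances small enough to enumerate, the tests require the
best of 20 runs to equal the exhaustive optimum. The reported objective
decomposition is always recomputed from the returned selection, never
carried over from the annealing state.

## Gap analysis

Protected-area polygons (GeoJSON) are rasterized by the cell-center rule
— at a 10-km analysis resolution the bias of ignoring partial cells is
bounded by one cell ring per polygon. The gap report computes overlap and
vacancy in area units, the percent of the priority area unprotected, and
a verdict against the conservation target. The bundled worked example
(`caseStudyAreas()`) reproduces the published fringe-tree arithmetic:
priority $38.50\times10^4$ km², overlap $1.93\times10^4$ km², gap
$36.57\times10^4$ km², 94.99% unprotected (the published table prints
94.98% from pre-rounded inputs; the package reports full precision).

## The synthetic landscape

The generator stands in for downloaded climate, soil, terrain, occurrence
and reserve data:

* **Predictors** are Gaussian white noise smoothed with a separable
  Gaussian kernel ($\sigma$ = `autocorrRange` cells, default 6),
  standardized to mean 0 / sd 1. Smoothing-kernel autocorrelation was
  chosen over spectral synthesis for simplicity and determinism.
  Collinear pairs are induced post hoc as
  $y = \rho x + \sqrt{1-\rho^2}\,z$, giving expected Pearson correlation
  exactly $\rho$; the default stack carries the 12 canonical
  bioclim/soil/terrain layers plus two extra bioclim layers correlated at
  0.85 and 0.90 with Bio4 and Bio6, so the screening stage (|r| ≥ 0.7,
  then VIF ≥ 5) has real work and reduces 14 layers to 12.
* **The niche** is a product of Gaussian responses. The default spans the
  four dominant variables of the emulated assessment (Bio6, Bio12, Bio4,
  Bio13) with optima (0.3, 0.0, −0.4, 0.2) in standardized units, common
  tolerance 0.4 and weights (1.0, 0.9, 0.8, 0.6). The tolerance is
  deliberately narrow: it represents a strongly climate-limited species
  and yields test AUCs near 0.93 — the regime of the assessment this
  package emulates (published test AUC 0.94). Baseline prevalence 0.95.
* **Occurrences** (default $n = 131$, the working presence count of the
  emulated assessment) are drawn without replacement proportionally to
  true suitability, at exact cell centers so thinning and extraction are
  bit-reproducible. A sampling-bias raster is supported but off by
  default; the emulated data described no bias structure.
* **Protected areas** are random axis-aligned rectangles whose common
  size scale is bisected until the rasterized union hits the requested
  coverage within ±10% relative.

What the generator does **not** emulate: the covariance structure of real
bioclim variables, future-climate deltas, realistic reserve geometry, or
observation error in coordinates. Passing tests therefore demonstrate
correctness of the algorithms and recoverability under the stated
statistical structure — not predictive skill on real occurrence data.

## Data-preparation conventions

* Thinning bins records into a fixed-origin grid anchored at
  (−180°, −90°), with the longitude bin width scaled by cos(latitude) of
  each record and 5 km as the default cell; the first record in input
  order is kept, making thinning deterministic and idempotent.
* Collinearity screening works on values at the occurrences plus a
  background sample (the modelling background mirrors what the
  correlations should describe). The pairwise stage processes offending
  pairs in decreasing |r| and drops the lower-priority member; the
  user-supplied priority ordering replaces the undefined "expert
  judgement" of typical workflows with an explicit, reproducible rule.
  The VIF stage then iteratively removes the highest-VIF variable; a
  perfectly collinear remainder collapses to a single variable rather
  than erroring.
* Cells are addressed row-major from the top-left with half-open
  intervals [edge, edge + size); coordinates are WGS84 throughout and no
  reprojection beyond geographic grids is attempted.

## Problem sizes and tolerances

The test-suite defaults are desk-scale by design: landscapes of 60×60
cells (100×100 for correlation checks, where the collinear-pair tolerance
of ±0.05 is reliable), background samples of 200–2000 cells, annealing
instances of ≤ 15 units (where exhaustive enumeration is the oracle) and
50,000 flips. The acceptance script runs the full pipeline on the default
100×100 landscape with 5 replicates and 2,500 planning units. Numeric
tolerances follow the quantity: exact combinatorial counts and hand
arithmetic at $10^{-9}$–$10^{-12}$, fitted coefficients against a
$10^{-4}$-step grid-search oracle at $10^{-3}$, stochastic recovery
properties asserted over three seeds.

## Known limitations

* The optimizer is plain cyclic coordinate descent; very large hinge
  designs (hundreds of features × $10^4$ background cells) fit in seconds
  to minutes, but no warm-starting across the tuning grid is attempted.
* Percent contribution depends on the update path, as in the reference
  implementation; it is reproducible but not unique.
* The annealer has no adaptive reheating; on large instances the solution
  is a good local optimum, with quality monitored through repeat runs and
  selection frequency.
* Future-scenario rasters must be supplied (or generated as perturbed
  predictors); no climate-model data handling is included.
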