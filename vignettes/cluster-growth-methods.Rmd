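---
title: "Modelling population change in residential clusters"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling population change in residential clusters}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(popclust)
```

`popclust` relates five-year population change in residential clusters —
connected patches of inhabited raster cells — to the clusters' geometry,
internal population distribution, and demography. This vignette is the
package's account of the method: the model and its assumptions, the
parameters that matter, the numerical choices, what the synthetic
generator does and does not emulate, and the known limitations.

## Units and coordinate conventions

The raster is abstracted to a planar integer grid: cell centres at integer
`(col, row)`, cell side = 1 distance unit. The physical side length (500 m
for a census mesh) is carried as metadata only. This is a deliberate
simplification: Roundness, Irregularity and CL are ratios that do not
depend on the physical side length, and at the sub-kilometre scale of a
mesh cell the difference between planar and geodesic distances is far
below the discreteness error of the raster itself. Whether inter-cell
distances in a geodetic data set should be projected first is a data-
preparation question outside the package; the grid-unit convention is the
package's substitute.

## Clusters and the dependent variable

A cell is populated if it holds at least one inhabitant. Clusters are
connected components of populated cells under the von Neumann
neighbourhood (4 side-sharing neighbours; diagonal contact does not
connect). Components are computed with a union-find over the adjacency
edge list — recursion-free, linear in the number of cells, and
order-independent; ids are assigned by row-major scan of each component's
minimum cell so that repeated runs produce identical tables.

The dependent variable is the follow-up population *inside the baseline
footprint*: clusters are never re-identified at follow-up for the
response. A cluster that splits, merges, or grows outward is still scored
on its original cell set, which deliberately discounts growth in newly
inhabited cells; follow-up inhabitants outside every baseline footprint
drop out of the analysis entirely. The minimum-area filter (default
`min_cells = 10`) removes clusters whose geometry is dominated by raster
discreteness; 10 cells is also the scale below which Roundness and
Irregularity take only a handful of distinct values.

## Morphology covariates

For a cluster with S cells, perimeter L, longest inter-cell-centre
distance d_max and per-cell counts n_i:

* **Roundness** = S / (π (d_max/2)²). Exact d_max is found by brute force
  over all cell pairs up to 2,000 cells; above that the convex hull is
  taken first and the maximum computed over hull vertices (the diameter of
  a finite point set is attained at hull vertices, so both paths are exact
  and are tested for agreement).
* **Irregularity** = 2 log L / log S, base-invariant (natural logs used).
  The perimeter counts *every* unit edge adjacent to a non-member cell,
  interior holes included. The package reads the index through the scaling
  relation S = L^(2/Irregularity) — a fractal dimension proxy — and a
  fractal boundary measure must count the full exposed boundary; this is
  the package's resolution of a genuinely open convention.
* **CL** = [Σ_{i<j} n_i n_j d_ij] / C(n, 2) / √S, the expected distance
  between two uniformly chosen inhabitants, normalised by √S. Same-cell
  pairs contribute distance 0 but remain in the C(n,2) denominator.
  Computed from the cell-pair distance matrix as a quadratic form, so the
  cost is O(S²), not O(n²) in the number of inhabitants.
* **Heterogeneity** = sample SD (divisor S − 1) over mean of the n_i. The
  sample convention is forced by the worked four-cell example the indices
  are anchored to: with 8 inhabitants over 4 cells, a CV of exactly 1.00
  requires counts (5,1,1,1) under the sample SD (the population SD caps at
  0.866).
* **Representative cell** for the region join: the member cell with the
  largest closeness centrality on the side-adjacency graph, computed as
  (number of other cells) / (sum of shortest-path lengths); any strictly
  monotone variant has the same argmax, which is all that is used. Ties —
  common in symmetric clusters — are resolved by averaging the tied cells'
  coordinates, which may land between cells; the region lookup therefore
  accepts fractional coordinates, and a point on a shared region edge goes
  to the lexicographically smallest region id, a deterministic tie rule.

Age and Tertiary are region-level attributes (the resolution at which such
covariates are typically published) joined from a caller-supplied table of
rectangular region footprints. The table is configuration data, not code;
a reverse-geocoding service is intentionally not part of the package.

## Regression models

The baseline count enters as a log offset with coefficient fixed at 1, so
exp(β₀) is the growth ratio of a reference cluster and every other
coefficient acts on relative growth. Area and Density are
log-transformed (both are heavy-tailed); their coefficients are
elasticities. The remaining covariates enter untransformed, and
`effect_transform()` converts their coefficients to multiplicative
effects.

The Poisson model is fit first. Its equal-mean-variance assumption is
checked with the Dean–Lawless score statistic
T = Σ[(y − μ̂)² − y] / √(2 Σ μ̂²), asymptotically N(0,1) under the
Poisson null, tested one-sided against overdispersion. The NB2 model
(variance μ + μ²/θ, a single θ for all clusters) is fit by alternating
IRLS for β and maximum likelihood for θ (`MASS::glm.nb`, log-likelihood
tolerance 1e-8, up to 50 outer iterations). On Poisson-like data θ
diverges; it is capped at 1e6 and flagged rather than treated as an error.
AIC counts θ as a parameter for the NB family.

Wald 95% intervals (estimate ± 1.96 SE) are reported throughout.
Univariate fits reuse the same offset, so univariate and multivariate
coefficients are on the same growth scale.

### Backward AIC selection

Selection starts from all 9 main effects plus all 36 pairwise
interactions. Covariates are mean-centred first — interactions of
uncentred covariates would be nearly collinear with their mains and
inflate VIFs — and an interaction column is the product of two centred
columns (not re-centred). At each step the single term whose removal most
decreases AIC is dropped; marginality is enforced (a main effect is not
removable while any of its interactions remains); selection stops when no
removal decreases AIC. By construction the accepted-step AIC trace is
non-increasing, and the suite asserts it.

Candidate deletions within a step are ranked with θ held at the current
model's estimate (a plain GLM fit per candidate), and only the chosen
model is refit by full ML with θ re-estimated; the step is accepted on the
full-ML AIC. Re-estimating θ for all ~40 candidates at every step would
multiply the cost by an order of magnitude and changes none of the
accepted steps in practice, since θ moves little under single-term
deletions.

Two properties of AIC-based backward selection are worth stating plainly.
A noise term survives a deletion test when its deviance contribution
exceeds 2 (probability ≈ 0.16 under the χ²₁ null), so with 45 starting
terms the selected model is essentially never empty even on pure noise —
the correct expectation is that the large majority of noise terms is
dropped, and that is what the suite checks. Conversely, a real term is
retained reliably only when it is identifiable: in the 45-term model most
interaction columns here are strongly collinear with one another, and a
coefficient of 0.05 is only detectable on an interaction involving a
covariate with a wide natural scale (Age, measured in years). The
selection-consistency test plants its interaction there for exactly this
reason.

## The synthetic generator

`generate_dataset()` emulates the features of gridded census data the
analysis actually relies on, at desk scale:

* **Shapes**: Eden-style stochastic growth (uniformly random boundary
  accretion) for compact blobs, with a per-step probability `elongation`
  of extending the shape at an extreme column instead; `elongation = 1`
  is an exact line. Cluster elongations are drawn uniformly on
  [0, `elongation`], spanning compact-to-line morphologies (Roundness
  from ~0.02 to ~1.1 in practice, matching the observed census range).
* **Areas**: discrete truncated Pareto, minimum 10, exponent 2.5, capped
  at 500 cells. The cap keeps desk-scale runs fast; real national meshes
  contain clusters two orders of magnitude larger.
* **Baseline allocation**: every cell gets 1 inhabitant (the cluster
  definition requires it); the remainder is multinomial with weights
  exp(−`concentration` · distance from the central cell) times log-normal
  noise with log-SD `heterogeneity_knob`. Concentration 0.5 and knob 0.6
  put the CL and Heterogeneity distributions near the census ranges;
  mean cell densities are log-normal (meanlog 3.5, sdlog 0.9, i.e.
  a median of ~33 inhabitants per cell).
* **Demography**: female counts binomial (p = 0.52); regions are vertical
  bands with Age ~ N(44.6, 1.2²) and Tertiary ~ N(0.65, 0.04²), the
  region-level resolution the analysis assumes.
* **Follow-up**: drawn from the NB2 law with the configured β
  (defaults of the same order as fitted census values) and θ = 5.

What it does *not* emulate: real geography (clusters are laid out on a
packing grid with a ≥ 2-cell buffer, so baseline clustering recovers the
generated clusters exactly), migration between clusters, spatial
autocorrelation between neighbouring clusters, terrain, or the extreme
upper tail of city sizes. Passing tests on synthetic grids therefore
demonstrate correctness of the accounting and calibration of the
inference under the model's own assumptions — not that the NB2 model is
an adequate description of any particular census.

## Problem sizes and determinism

All randomness flows from explicit integer seeds (`synthetic_config()`
refuses a missing seed); grids and report bundles are byte-identical
across runs. The statistical suites use: 200 random polyominoes (≤ 25
cells) for oracle equivalence; 500 Poisson-null replicates of N = 1000
for the overdispersion test's type-I error; one 2000-cluster grid with
100 follow-up redraws for CI calibration (coverage of the generating
coefficients conditional on the realized design — the standard check for
a regression's interval calibration) plus one full end-to-end recovery
run; and 50 selection replicates at N = 2000 for the planted-interaction
check. These sizes put Monte-Carlo error comfortably below the margins
being asserted while keeping a full run of the suite in the tens of
minutes.

## Limitations

* Footprint accounting discounts genuine growth that spills outside the
  baseline footprint, and ignores follow-up inhabitants in newly settled
  areas; totals across clusters at follow-up are therefore a lower bound.
* Age and Tertiary are region-level, so within-region variation between
  clusters is invisible to the model.
* Clusters are treated as independent: no migration flows, no spatial
  autocorrelation between clusters, no gravity-style interaction.
* The region join uses rectangular footprints; arbitrary polygonal
  regions must be approximated by rectangles or resolved upstream.
* Single-cell morphology is undefined (d_max = 0, log S = 0); such
  clusters are excluded by the min-area filter long before it matters.
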