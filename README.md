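# popclust

Where does local population grow, and where does it shrink? `popclust`
analyses five-year population change in *residential clusters* — connected
patches of inhabited cells on a raster population grid — and asks how much
of that change is explained by the cluster's geometry and internal
population distribution, beyond its size and demography. It is aimed at
spatial demographers and regional scientists working with gridded census
data (for example a 500 m × 500 m national mesh observed at two censuses).

## The method

**Clusters.** A cluster is a connected component of populated cells
(female + male ≥ 1) under the von Neumann neighbourhood (side-sharing
cells only; diagonal contact does not connect). Clusters are identified at
the baseline census; the follow-up population of a cluster is counted
inside the *same* cell footprint, so splits, merges and growth beyond the
footprint are deliberately ignored. Clusters of fewer than 10 cells are
excluded (raster discreteness dominates their geometry).

**Per-cluster covariates.** With S the area in cells, L the perimeter in
cell-side units (interior holes included), d_max the longest distance
between cell centres, and n_i the per-cell counts:

- *Roundness* = S / (π (d_max/2)²) — disc-like clusters score high;
- *Irregularity* = 2 log L / log S — a perimeter-based fractal-dimension
  proxy (S = L^(2/Irregularity)), small for square-like clusters;
- *CL* (characteristic length) = E[distance between two random
  inhabitants] / √S = [Σ_{i<j} n_i n_j d_ij] / C(n,2) / √S — small when
  population concentrates near the cluster centre;
- *Heterogeneity* = coefficient of variation of the per-cell counts
  (sample SD / mean);
- *Density* = n/S, *Gender* = female fraction, and region-level *Age* and
  *Tertiary* (mean age, tertiary-industry worker fraction) joined at the
  cluster's most central cell (largest closeness centrality, ties
  averaged).

**Model.** The follow-up count ñ_c is modelled as negative binomial (NB2)
with log link and the log baseline population as a unit-coefficient
offset:

    log μ_c = log n_c + β₀ + β₁ log(Area) + β₂ log(Density) + Σᵢ βᵢ Xᵢ,
    Var(ñ_c) = μ_c + μ_c²/θ,

so the model describes *relative* growth. A Poisson fit is run first and
checked with the Dean–Lawless overdispersion score statistic
T = Σ[(y−μ̂)²−y] / √(2Σμ̂²) ~ N(0,1); overdispersion motivates the NB
model. The pipeline also produces univariate fits, Pearson / Spearman /
Kendall correlation tables, VIFs, backward-AIC selection over all main
effects and mean-centred pairwise interactions (respecting marginality),
and an OLS regression of log growth on log baseline size.

A synthetic-grid generator (`synthetic_config()`, `generate_dataset()`)
produces clusters with controllable shape, concentration and heterogeneity
and draws follow-up counts from the NB2 law with known coefficients, so
the whole pipeline is testable without census data.

## Worked example

```r
library(popclust)

# the four-cell S-tetromino: longest centre distance sqrt(5)
m <- cbind(col = c(0, 0, 1, 1), row = c(0, 1, 1, 2))
round(cluster_roundness(m), 3)
#> [1] 1.019
cluster_heterogeneity(c(5, 1, 1, 1))
#> [1] 1

# simulate 200 clusters and run the full analysis
cfg <- synthetic_config(n_clusters = 200, seed = 7)
res <- run_pipeline(synthetic = cfg)
res$negbin
#> Negative binomial regression with log-baseline offset (N = 200)
#>               estimate     se ci_lower ci_upper
#> (Intercept)    -0.1558 0.0304  -0.2154  -0.0962
#> log_area        0.0861 0.1381  -0.1846   0.3567
#> log_density     0.0735 0.0366   0.0019   0.1452
#> ...
#> theta = 5.498
#> logLik = -1375.22, AIC = 2772.44
```

The intercept is the log growth ratio of an average cluster (covariates
are mean-centred by default); `theta` is the NB2 dispersion — the
generating value in this simulation was 5. Coefficients on the logged
covariates are elasticities (a 1% increase in Density is associated with a
0.0735% increase in follow-up population here); for the others,
`effect_transform()` converts a coefficient into a multiplicative effect,
e.g. `effect_transform(-0.0327, 0.01, "decrease_fraction")` = 3.27e-4.

A shell entry point wraps the same pipeline:

```sh
Rscript scripts/run_pipeline.R --simulate --n-clusters 200 --seed 7 --out report/
Rscript scripts/run_pipeline.R --grid grid.csv --regions regions.csv \
  --baseline-year 2005 --followup-year 2010 --out report/
```

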