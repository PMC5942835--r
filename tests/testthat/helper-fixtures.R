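# Fixtures built in code.

# Quick grid builder: one year's worth of cells, all-female counts.
make_grid <- function(col, row, pop, year = 1, years = NULL) {
  population_grid(
    data.frame(col = col, row = row, year = year, female = pop,
               male = 0L),
    years = years
  )
}

# The hypothetical worked example: a five-cell baseline cluster with
# populations 10,20,30,40,50; at follow-up only three footprint cells remain
# populated (10, 15, 60) and a new cell outside the footprint appears.
fig1_grid <- function() {
  baseline <- data.frame(
    col = c(0, 1, 1, 2, 2), row = c(0, 0, 1, 1, 2),
    year = 2005, female = c(10, 20, 30, 40, 50), male = 0
  )
  followup <- data.frame(
    col = c(0, 1, 2, 4), row = c(0, 0, 2, 0),
    year = 2010, female = c(10, 15, 60, 7), male = 0
  )
  population_grid(rbind(baseline, followup), years = c(2005, 2010))
}

# One region covering everything.
whole_region <- function(age = 44.6, tertiary = 0.65) {
  region_table(data.frame(
    region_id = "R1", mean_age = age, tertiary_fraction = tertiary,
    col_min = -1000, col_max = 1000, row_min = -1000, row_max = 1000
  ))
}

# A small synthetic feature table (deterministic given seed).
small_features <- function(n_clusters = 60, seed = 1, ...) {
  cfg <- synthetic_config(n_clusters = n_clusters, seed = seed, ...)
  generate_dataset(cfg)$truth$features
}

# Feature table whose nine covariate columns are exactly a supplied matrix
# (columns orthogonal tricks etc.); n_baseline/n_followup arbitrary valid.
features_from_X <- function(X) {
  stopifnot(ncol(X) == 9)
  data.frame(
    cluster_id = seq_len(nrow(X)),
    n_baseline = 100L,
    n_followup = 100L,
    S = exp(X[, 1] + 3),      # location shifts leave correlations and
    density = exp(X[, 2] + 3),  # VIFs unchanged; keeps S >= 1

    L = 8,
    roundness = X[, 3],
    irregularity = X[, 4],
    cl = X[, 5],
    heterogeneity = X[, 6],
    gender = X[, 7],
    age = X[, 8],
    tertiary = X[, 9]
  )
}

# n x 9 matrix with orthonormal columns, each orthogonal to the intercept.
orthonormal_X <- function(n, seed = 42) {
  set.seed(seed)
  q <- qr.Q(qr(cbind(1, matrix(rnorm(n * 9), n, 9))))[, -1]
  colnames(q) <- c("log_area", "log_density", "roundness", "irregularity",
                   "cl", "heterogeneity", "gender", "age", "tertiary")
  q
}

# Bare model-matrix object (bypasses feature-table plumbing) for fits with
# hand-built covariates.
raw_mm <- function(response, offset, X = NULL) {
  if (is.null(X)) {
    X <- matrix(numeric(0), nrow = length(response), ncol = 0)
  }
  structure(
    list(response = response, offset = offset, X = X,
         centered = FALSE,
         means = stats::setNames(rep(0, ncol(X)), colnames(X)),
         cluster_id = seq_along(response)),
    class = "model_matrix"
  )
}
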