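#' Synthetic-study configuration
#'
#' Parameters of the synthetic population-grid generator.  The generator
#' emulates the statistical structure the analysis assumes: connected
#' clusters spanning compact-to-line shapes, heavy-tailed areas and
#' populations, population concentrated towards cluster centres, region
#' (prefecture-analogue) labels, and follow-up counts drawn from the NB2
#' growth law with known coefficients.
#'
#' Defaults mirror the study conditions of the census analysis at desk
#' scale: minimum cluster area 10 cells, Pareto-tailed areas (exponent 2.5,
#' capped at 500 cells), log-normal cell densities around ~33 inhabitants
#' per cell, female fraction 0.52, regional mean ages around 44.6 years and
#' tertiary fractions around 0.65, and growth coefficients of the same
#' order as the fitted census values with dispersion `theta = 5`.
#'
#' @param n_clusters number of clusters to generate.
#' @param area_min,area_max,area_exponent discrete Pareto law for cluster
#'   areas: `P(A >= a) ~ a^(1 - area_exponent)` truncated to
#'   `[area_min, area_max]`.
#' @param elongation maximum elongation; each cluster draws its own
#'   elongation uniformly from `[0, elongation]` (0 = Eden-growth blob,
#'   1 = straight line), spanning the observed roundness range.
#' @param concentration distance-decay rate of expected population from the
#'   cluster's central cell (per cell-side unit).
#' @param heterogeneity_knob log-SD of multiplicative cell-weight noise;
#'   0 gives near-uniform counts.
#' @param density_meanlog,density_sdlog log-normal law for mean inhabitants
#'   per cell of a cluster.
#' @param gender_mean expected female fraction.
#' @param n_regions number of vertical region bands covering the canvas.
#' @param age_mean,age_sd,tertiary_mean,tertiary_sd regional attribute laws.
#' @param beta numeric length-10 growth coefficients
#'   `(b0, log_area, log_density, roundness, irregularity, cl,
#'   heterogeneity, gender, age, tertiary)` on the *uncentred* covariates.
#' @param theta NB2 dispersion (> 0).
#' @param seed integer seed; mandatory, every draw derives from it.
#' @return An object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_clusters = 100,
                             area_min = 10,
                             area_max = 500,
                             area_exponent = 2.5,
                             elongation = 1,
                             concentration = 0.5,
                             heterogeneity_knob = 0.6,
                             density_meanlog = 3.5,
                             density_sdlog = 0.9,
                             gender_mean = 0.52,
                             n_regions = 5,
                             age_mean = 44.6, age_sd = 1.2,
                             tertiary_mean = 0.65, tertiary_sd = 0.04,
                             beta = c(0.0, 0.011, 0.023, 0.004, -0.033,
                                      -0.036, -0.001, -0.043, -0.0024,
                                      -0.0098),
                             theta = 5,
                             seed) {
  if (missing(seed)) stop("seed is mandatory")
  stopifnot(n_clusters >= 1, area_min >= 1, area_max >= area_min,
            area_exponent > 1, elongation >= 0, elongation <= 1,
            concentration >= 0, heterogeneity_knob >= 0,
            gender_mean >= 0, gender_mean <= 1,
            length(beta) == 10, theta > 0)
  structure(as.list(environment()), class = "synthetic_config")
}

#' Grow a connected cluster shape
#'
#' `elongation = 1` returns an exact `1 x area` line.  Otherwise the shape
#' grows Eden-style from a seed cell — at each step a uniformly random empty
#' neighbour of the current shape is added — except that with probability
#' `elongation` the step instead extends the shape at its extreme columns,
#' which interpolates towards line-like clusters.  Output is always
#' connected under the von Neumann neighbourhood.
#'
#' Consumes the session RNG; seed with [set.seed()] for reproducibility.
#'
#' @param area number of cells (>= 1).
#' @param elongation in `[0, 1]`.
#' @return Two-column integer matrix of cell coordinates.
#' @export
generate_shape <- function(area, elongation = 0) {
  stopifnot(area >= 1, elongation >= 0, elongation <= 1)
  if (elongation >= 1 || area <= 2) {
    return(cbind(col = seq_len(area) - 1L, row = rep(0L, area)))
  }
  # canvas large enough for any growth path
  half <- as.integer(area + 2L)
  size <- 2L * half + 1L
  occ <- matrix(FALSE, nrow = size, ncol = size)  # [row, col], 1-based
  enc <- function(col, row) cbind(row + half + 1L, col + half + 1L)
  cells <- matrix(c(0L, 0L), ncol = 2,
                  dimnames = list(NULL, c("col", "row")))
  occ[enc(0L, 0L)] <- TRUE
  nbr <- rbind(c(1L, 0L), c(-1L, 0L), c(0L, 1L), c(0L, -1L))
  frontier <- sweep(nbr, 2, c(0L, 0L), "+")
  while (nrow(cells) < area) {
    if (stats::runif(1) < elongation) {
      # step outward from a cell at an extreme column to elongate the shape
      grow_right <- stats::runif(1) < 0.5
      edge_col <- if (grow_right) max(cells[, 1]) else min(cells[, 1])
      rows_edge <- cells[cells[, 1] == edge_col, 2]
      new_cell <- c(edge_col + (if (grow_right) 1L else -1L),
                    rows_edge[sample.int(length(rows_edge), 1)])
      if (occ[enc(new_cell[1], new_cell[2])]) next
    } else {
      repeat {
        i <- sample.int(nrow(frontier), 1)
        new_cell <- frontier[i, ]
        if (!occ[enc(new_cell[1], new_cell[2])]) break
        frontier <- frontier[-i, , drop = FALSE]
      }
    }
    occ[enc(new_cell[1], new_cell[2])] <- TRUE
    cells <- rbind(cells, new_cell)
    cand <- sweep(nbr, 2, new_cell, "+")
    cand <- cand[!occ[enc(cand[, 1], cand[, 2])], , drop = FALSE]
    frontier <- rbind(frontier, cand)
  }
  dimnames(cells) <- list(NULL, c("col", "row"))
  cells
}

#' Allocate a baseline population over a cluster shape
#'
#' Every cell receives at least one inhabitant; the remaining
#' `total - |shape|` inhabitants are distributed multinomially with cell
#' weights `exp(-concentration * d_i)` where `d_i` is the Euclidean
#' distance from the cluster's most central cell, times multiplicative
#' log-normal noise with log-SD `heterogeneity_knob`.  Higher concentration
#' pulls population towards the centre (lowering CL); higher noise raises
#' the within-cluster CV.  Female counts are binomial with success
#' probability `gender_mean`.
#'
#' Consumes the session RNG.
#'
#' @param shape two-column cell matrix from [generate_shape()].
#' @param total total inhabitants (>= number of cells).
#' @param concentration,heterogeneity_knob,gender_mean see
#'   [synthetic_config()].
#' @return Data frame `col`, `row`, `female`, `male`.
#' @export
allocate_baseline_population <- function(shape, total, concentration = 0,
                                         heterogeneity_knob = 0,
                                         gender_mean = 0.5) {
  s <- nrow(shape)
  if (total < s) {
    stop("total population ", total, " is below the cell count ", s)
  }
  ctr <- central_cell(shape)
  d <- sqrt((shape[, 1] - ctr[["col"]])^2 + (shape[, 2] - ctr[["row"]])^2)
  w <- exp(-concentration * d)
  if (heterogeneity_knob > 0) {
    w <- w * stats::rlnorm(s, meanlog = 0, sdlog = heterogeneity_knob)
  }
  extra <- as.integer(stats::rmultinom(1, total - s, prob = w))
  counts <- 1L + extra
  female <- stats::rbinom(s, size = counts, prob = gender_mean)
  data.frame(col = shape[, 1], row = shape[, 2],
             female = female, male = counts - female)
}

#' Draw follow-up cluster populations from the NB2 growth law
#'
#' For each cluster, `mu_c = n_baseline * exp(b0 + sum_i b_i X_i)` on the
#' uncentred covariates (log Area, log Density, roundness, irregularity,
#' CL, heterogeneity, gender, age, tertiary), and the follow-up count is
#' negative binomial with mean `mu_c` and variance `mu_c + mu_c^2 / theta`.
#'
#' Consumes the session RNG.
#'
#' @param features feature table (the baseline truth).
#' @param beta length-10 coefficient vector (intercept first).
#' @param theta NB2 dispersion.
#' @return Integer vector of follow-up counts aligned with `features` rows.
#' @export
simulate_followup <- function(features, beta, theta) {
  stopifnot(length(beta) == 10, theta > 0)
  X <- build_model_matrix(transform(features, n_followup = 0))$X
  eta <- beta[1] + as.numeric(X %*% beta[-1])
  mu <- features$n_baseline * exp(eta)
  if (any(!is.finite(mu)) || any(mu > 2^52)) {
    stop("follow-up mean overflow for cluster ",
         features$cluster_id[which(!is.finite(mu) | mu > 2^52)[1]])
  }
  stats::rnbinom(length(mu), size = theta, mu = mu)
}

#' Generate a complete synthetic data set
#'
#' Lays out `n_clusters` shapes on a shared canvas with at least two empty
#' cells between any two clusters (so the clustering stage recovers exactly
#' the generated clusters), allocates baseline populations, covers the
#' canvas with vertical region bands carrying age and tertiary attributes,
#' computes the true per-cluster features, and draws follow-up counts from
#' the NB2 law with the configured coefficients.  Fully reproducible from
#' `config$seed`.
#'
#' @param config a [synthetic_config()].
#' @return List with `grid` (a [population_grid()], years 1 and 2),
#'   `regions` (a [region_table()]), and `truth` (list: `beta`, `theta`,
#'   `seed`, and the realized `features` table).
#' @export
generate_dataset <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed)
  n <- config$n_clusters

  # heavy-tailed areas: discrete truncated Pareto via inverse CDF
  u <- stats::runif(n)
  a <- config$area_exponent - 1
  lo <- config$area_min; hi <- config$area_max
  raw <- lo * (1 - u * (1 - (lo / hi)^a))^(-1 / a)
  areas <- pmin(as.integer(floor(raw)), as.integer(hi))

  elong <- stats::runif(n, 0, config$elongation)
  shapes <- vector("list", n)
  for (i in seq_len(n)) {
    shapes[[i]] <- generate_shape(areas[i], elong[i])
  }

  # row-wise shelf packing with a 3-cell gap guarantees a >= 2-cell buffer
  canvas_w <- max(60L, as.integer(ceiling(3 * sqrt(sum(areas + 9)))))
  gap <- 3L
  x <- 0L; y <- 0L; shelf_h <- 0L
  cells_list <- vector("list", n)
  for (i in seq_len(n)) {
    sh <- shapes[[i]]
    sh[, 1] <- sh[, 1] - min(sh[, 1])
    sh[, 2] <- sh[, 2] - min(sh[, 2])
    w_i <- max(sh[, 1]) + 1L
    h_i <- max(sh[, 2]) + 1L
    if (x + w_i > canvas_w && x > 0L) {
      x <- 0L
      y <- y + shelf_h + gap
      shelf_h <- 0L
    }
    sh[, 1] <- sh[, 1] + x
    sh[, 2] <- sh[, 2] + y
    cells_list[[i]] <- sh
    x <- x + w_i + gap
    shelf_h <- max(shelf_h, h_i)
  }
  canvas_h <- y + shelf_h

  dens <- stats::rlnorm(n, config$density_meanlog, config$density_sdlog)
  totals <- pmax(areas, as.integer(round(dens * areas)))

  cell_rows <- vector("list", n)
  for (i in seq_len(n)) {
    cell_rows[[i]] <- allocate_baseline_population(
      cells_list[[i]], totals[i],
      concentration = config$concentration,
      heterogeneity_knob = config$heterogeneity_knob,
      gender_mean = config$gender_mean
    )
  }
  baseline <- do.call(rbind, cell_rows)
  baseline$year <- 1L

  # vertical region bands covering the canvas
  k <- config$n_regions
  bounds <- unique(as.integer(round(seq(0, canvas_w, length.out = k + 1))))
  k <- length(bounds) - 1
  regions <- data.frame(
    region_id = sprintf("R%02d", seq_len(k)),
    mean_age = round(stats::rnorm(k, config$age_mean, config$age_sd), 1),
    tertiary_fraction = round(
      pmin(1, pmax(0, stats::rnorm(k, config$tertiary_mean,
                                   config$tertiary_sd))), 3),
    col_min = bounds[-(k + 1)],
    col_max = pmax(bounds[-(k + 1)], bounds[-1] - 1L),
    row_min = 0L,
    row_max = as.integer(canvas_h + 1L)
  )
  rt <- region_table(regions)

  grid1 <- population_grid(baseline, years = c(1L, 2L))
  clusters <- find_clusters(grid1, 1L)
  features <- build_feature_table(
    clusters, grid1, rt, baseline = 1L, followup = 2L
  )
  followup_counts <- simulate_followup(features, config$beta, config$theta)
  features$n_followup <- followup_counts

  # write the follow-up counts back onto the grid: keep each cluster's
  # within-footprint distribution proportional to baseline
  fu_rows <- vector("list", n_clusters(clusters))
  ids <- sort(unique(clusters$cluster_id))
  for (k2 in seq_along(ids)) {
    m <- cluster_cells(clusters, ids[k2])
    base <- baseline[match(paste(m[, 1], m[, 2]),
                           paste(baseline$col, baseline$row)), ]
    tot <- base$female + base$male
    alloc <- as.integer(stats::rmultinom(1, followup_counts[k2], prob = tot))
    fem <- stats::rbinom(length(alloc), size = alloc,
                         prob = config$gender_mean)
    fu_rows[[k2]] <- data.frame(col = m[, 1], row = m[, 2],
                                female = fem, male = alloc - fem,
                                year = 2L)
  }
  followup <- do.call(rbind, fu_rows)
  followup <- followup[followup$female + followup$male >= 1, , drop = FALSE]

  all_cells <- rbind(baseline[, c("col", "row", "year", "female", "male")],
                     followup[, c("col", "row", "year", "female", "male")])
  grid <- population_grid(all_cells, years = c(1L, 2L))

  list(grid = grid,
       regions = rt,
       truth = list(beta = config$beta, theta = config$theta,
                    seed = config$seed, features = features))
}
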