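#' @title Cluster morphology and demography indices
#' @description
#' Per-cluster covariates for the growth regression.  Throughout, a cluster
#' is a set of cells given as a two-column matrix of integer coordinates
#' (`col`, `row`); cell centres sit at the integer coordinates and all
#' distances are Euclidean in cell-side units.
#' @name morphology
NULL

as_cell_matrix <- function(cells) {
  m <- as.matrix(cells)
  if (ncol(m) != 2) stop("cells must be a two-column (col,row) matrix")
  storage.mode(m) <- "double"
  dimnames(m) <- list(NULL, c("col", "row"))
  m
}

#' Longest pairwise distance between cluster cells
#'
#' Maximum Euclidean distance between the centres of any two member cells.
#' For clusters up to 2,000 cells the maximum is taken by brute force over
#' all pairs; larger clusters go through the convex hull first (the diameter
#' is attained between hull vertices), which is exact and fast.  A
#' single-cell cluster is degenerate and returns 0.
#'
#' @param cells two-column matrix of cell coordinates.
#' @return Distance in cell-side units.
#' @export
longest_pairwise_distance <- function(cells) {
  m <- as_cell_matrix(cells)
  if (nrow(m) < 2) {
    return(0)
  }
  if (nrow(m) > 2000) {
    h <- grDevices::chull(m)
    m <- m[h, , drop = FALSE]
  }
  max(stats::dist(m))
}

#' Roundness of a cluster
#'
#' Cluster area S (cell count) divided by the area of the circle whose
#' diameter is the longest inter-cell-centre distance:
#' `S / (pi * (d_max / 2)^2)`.  Disc-like clusters score high; for a given
#' area, a line scores lowest.  Undefined (NA) for a single cell.
#'
#' @inheritParams longest_pairwise_distance
#' @return Dimensionless roundness, or `NA` for a degenerate cluster.
#' @export
cluster_roundness <- function(cells) {
  m <- as_cell_matrix(cells)
  s <- nrow(m)
  d <- longest_pairwise_distance(m)
  if (d == 0) {
    return(NA_real_)
  }
  s / (pi * (d / 2)^2)
}

#' Perimeter of a cluster
#'
#' Number of unit cell edges adjacent to a non-member cell.  Interior hole
#' boundaries count as well as the outer boundary, consistent with reading
#' the irregularity index as a fractal-dimension proxy (total exposed
#' boundary).  Computed as `4 S - 2 A` where `A` is the number of
#' side-adjacent member pairs.
#'
#' @inheritParams longest_pairwise_distance
#' @return Perimeter in cell-side units (an even integer >= 4).
#' @export
cluster_perimeter <- function(cells) {
  m <- as_cell_matrix(cells)
  key <- paste(m[, 1], m[, 2])
  east <- paste(m[, 1] + 1, m[, 2])
  north <- paste(m[, 1], m[, 2] + 1)
  adj <- sum(east %in% key) + sum(north %in% key)
  4 * nrow(m) - 2 * adj
}

#' Irregularity of a cluster
#'
#' `2 * log(L) / log(S)` with L the perimeter and S the area; the ratio is
#' independent of the logarithm base (natural logs used).  Through the
#' scaling relation `S = L^(2/Irregularity)` it acts as a perimeter-based
#' fractal dimension: small for square-like clusters, large for ragged or
#' line-like ones.  Undefined (NA) for a single cell (log S = 0).
#'
#' @inheritParams longest_pairwise_distance
#' @return Dimensionless irregularity, or `NA` for a single cell.
#' @export
cluster_irregularity <- function(cells) {
  m <- as_cell_matrix(cells)
  s <- nrow(m)
  if (s < 2) {
    return(NA_real_)
  }
  2 * log(cluster_perimeter(m)) / log(s)
}

#' Characteristic length of a cluster
#'
#' Expected Euclidean distance between two uniformly randomly chosen
#' inhabitants of the cluster, divided by `sqrt(S)` to make it (for
#' two-dimensional clusters) dimensionless:
#' `CL = [sum_{i<j} n_i n_j d_ij] / choose(n, 2) / sqrt(S)`
#' where `n_i` are per-cell counts, `n` the cluster population, and same-cell
#' pairs contribute distance 0 (they are covered by the `choose(n, 2)`
#' denominator).  CL is small when population concentrates near the
#' cluster's geometric centre.  Undefined (NA) when the cluster has fewer
#' than two inhabitants.
#'
#' @inheritParams longest_pairwise_distance
#' @param pops per-cell inhabitant counts, aligned with `cells` rows.
#' @return Dimensionless characteristic length, or `NA` if degenerate.
#' @export
characteristic_length <- function(cells, pops) {
  m <- as_cell_matrix(cells)
  stopifnot(length(pops) == nrow(m))
  n <- sum(pops)
  if (n < 2) {
    return(NA_real_)
  }
  d <- as.matrix(stats::dist(m))
  total <- as.numeric(pops %*% d %*% pops) / 2  # sum_{i<j} n_i n_j d_ij
  total / choose(n, 2) / sqrt(nrow(m))
}

#' Heterogeneity of the within-cluster population distribution
#'
#' Coefficient of variation of the per-cell inhabitant counts: sample
#' standard deviation (divisor S - 1) divided by the mean.  Zero iff all
#' member cells hold equal counts.  Undefined (NA) for a single cell.
#'
#' @param pops per-cell inhabitant counts.
#' @return Dimensionless CV, or `NA` for a single cell.
#' @export
cluster_heterogeneity <- function(pops) {
  if (length(pops) < 2) {
    return(NA_real_)
  }
  stats::sd(pops) / mean(pops)
}

#' Fraction of female inhabitants in a cluster
#'
#' @param female,male per-cell counts, aligned.
#' @return Fraction in `[0, 1]`.
#' @export
gender_fraction <- function(female, male) {
  tot <- sum(female) + sum(male)
  if (tot == 0) {
    stop("cluster has zero inhabitants; gender fraction undefined")
  }
  sum(female) / tot
}

#' Representative (most central) cell of a cluster
#'
#' Closeness centrality on the unweighted graph whose nodes are the member
#' cells and whose edges join side-sharing cells: a node's closeness is the
#' number of other nodes divided by the sum of its shortest-path distances
#' to them.  Returns the centre of the argmax cell; when several cells tie
#' for the largest closeness, the mean coordinate of the tied cells (which
#' may be fractional).
#'
#' @inheritParams longest_pairwise_distance
#' @return Numeric length-2 vector `(col, row)`.
#' @export
central_cell <- function(cells) {
  m <- as_cell_matrix(cells)
  s <- nrow(m)
  if (s == 1) {
    return(c(col = unname(m[1, 1]), row = unname(m[1, 2])))
  }
  d <- lattice_distances(m)
  tot <- rowSums(d)
  best <- which(abs(tot - min(tot)) < 1e-9)  # min total distance = max closeness
  c(col = mean(m[best, 1]), row = mean(m[best, 2]))
}

# All-pairs shortest-path lengths on the side-adjacency graph of a cell set.
lattice_distances <- function(m) {
  g <- lattice_graph(m)
  igraph::distances(g)
}

lattice_graph <- function(m) {
  key <- paste(m[, 1], m[, 2])
  east <- match(paste(m[, 1] + 1, m[, 2]), key)
  north <- match(paste(m[, 1], m[, 2] + 1), key)
  from <- c(seq_len(nrow(m))[!is.na(east)], seq_len(nrow(m))[!is.na(north)])
  to <- c(east[!is.na(east)], north[!is.na(north)])
  g <- igraph::make_empty_graph(nrow(m), directed = FALSE)
  igraph::add_edges(g, rbind(from, to))
}

#' Region attributes at a cluster's representative cell
#'
#' Joins the cluster to the region (prefecture analogue) containing its most
#' central cell, returning that region's mean inhabitant age and
#' tertiary-industry worker fraction.
#'
#' @inheritParams longest_pairwise_distance
#' @param table a [region_table()].
#' @return Named list `age`, `tertiary`, `region_id`.
#' @export
assign_region_attributes <- function(cells, table) {
  ctr <- central_cell(cells)
  rid <- region_lookup(table, ctr[["col"]], ctr[["row"]])
  if (is.na(rid)) {
    stop("central cell (", ctr[["col"]], ",", ctr[["row"]],
         ") lies in no region; extend the region table to cover it")
  }
  r <- table$regions[table$regions$region_id == rid, , drop = FALSE]
  list(age = r$mean_age, tertiary = r$tertiary_fraction, region_id = rid)
}

#' Build the per-cluster feature table
#'
#' One row per cluster with every covariate of the growth regression:
#' baseline and follow-up footprint populations, area `S`, density
#' (inhabitants per cell), perimeter `L`, roundness, irregularity,
#' characteristic length, heterogeneity, gender fraction, and region-joined
#' age and tertiary fraction.  Log transforms are *not* applied here; the
#' model-matrix builder owns them.
#'
#' @param clusters a `cluster_set`, normally after [filter_min_area()].
#' @param grid a [population_grid()] with both years.
#' @param region_table a [region_table()] covering the grid.
#' @param baseline,followup year labels; default to `grid$years`.
#' @return Data frame with columns `cluster_id`, `n_baseline`, `n_followup`,
#'   `S`, `density`, `L`, `roundness`, `irregularity`, `cl`,
#'   `heterogeneity`, `gender`, `age`, `tertiary`.
#' @export
build_feature_table <- function(clusters, grid, region_table,
                                baseline = grid$years[1],
                                followup = grid$years[2]) {
  growth <- footprint_populations(clusters, grid, baseline, followup)
  base_cells <- populated_cells(grid, baseline)
  bkey <- paste(base_cells$col, base_cells$row)
  ids <- growth$cluster_id
  rows <- vector("list", length(ids))
  for (k in seq_along(ids)) {
    m <- cluster_cells(clusters, ids[k])
    pos <- match(paste(m[, 1], m[, 2]), bkey)
    pops <- base_cells$pop[pos]
    s <- nrow(m)
    feat <- data.frame(
      cluster_id = ids[k],
      n_baseline = growth$n_baseline[k],
      n_followup = growth$n_followup[k],
      S = s,
      density = growth$n_baseline[k] / s,
      L = cluster_perimeter(m),
      roundness = cluster_roundness(m),
      irregularity = cluster_irregularity(m),
      cl = characteristic_length(m, pops),
      heterogeneity = cluster_heterogeneity(pops),
      gender = gender_fraction(base_cells$female[pos], base_cells$male[pos])
    )
    reg <- assign_region_attributes(m, region_table)
    feat$age <- reg$age
    feat$tertiary <- reg$tertiary
    rows[[k]] <- feat
  }
  out <- do.call(rbind, rows)
  bad <- which(!stats::complete.cases(out))
  if (length(bad) > 0) {
    stop("undefined feature for cluster ", out$cluster_id[bad[1]],
         " (degenerate geometry or population)")
  }
  rownames(out) <- NULL
  out
}

#' Write a feature table to CSV
#'
#' @param features data frame from [build_feature_table()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_feature_csv <- function(features, path) {
  cols <- c("cluster_id", "n_baseline", "n_followup", "S", "density", "L",
            "roundness", "irregularity", "cl", "heterogeneity", "gender",
            "age", "tertiary")
  utils::write.csv(features[, cols], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
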