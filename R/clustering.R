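#' Identify inhabited clusters (city clustering algorithm)
#'
#' A cluster is a connected component of populated cells (female + male >= 1)
#' under the von Neumann neighbourhood: cells are adjacent iff they share a
#' side; diagonal contact does not connect.  Components are found with a
#' union-find over the side-adjacency edge list, so the partition is
#' independent of cell input order.  Cluster ids are assigned by row-major
#' scanning order of each component's minimum cell, which makes them stable
#' across runs and joinable.
#'
#' @param grid a [population_grid()].
#' @param year year label at which to cluster (normally the baseline year).
#' @return An object of class `cluster_set`: a data frame with columns
#'   `cluster_id`, `col`, `row` (one row per member cell), with the
#'   clustering year in attribute `year`.
#' @export
find_clusters <- function(grid, year) {
  cells <- populated_cells(grid, year)
  if (nrow(cells) == 0) {
    out <- data.frame(cluster_id = integer(), col = integer(),
                      row = integer())
    attr(out, "year") <- year
    class(out) <- c("cluster_set", "data.frame")
    return(out)
  }
  n <- nrow(cells)
  # encode (col,row) as a single integer key for O(1) neighbour lookup
  cmin <- min(cells$col); rmin <- min(cells$row)
  w <- max(cells$col) - cmin + 2L
  key <- (cells$row - rmin) * w + (cells$col - cmin)
  east <- match(key + 1L, key)
  north <- match(key + w, key)
  parent <- seq_len(n)
  find_root <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]  # path halving
      i <- parent[i]
    }
    i
  }
  link <- function(a, b) {
    ra <- find_root(a); rb <- find_root(b)
    if (ra != rb) parent[max(ra, rb)] <<- min(ra, rb)
  }
  for (i in seq_len(n)) {
    if (!is.na(east[i])) link(i, east[i])
    if (!is.na(north[i])) link(i, north[i])
  }
  root <- vapply(seq_len(n), find_root, integer(1))
  # stable ids: order components by the row-major position of their minimum
  # cell (smallest row, then col)
  rowmajor <- key  # already row-major rank within the bounding box
  comp_min <- tapply(rowmajor, root, min)
  comp_rank <- rank(comp_min, ties.method = "first")
  id_of_root <- stats::setNames(as.integer(comp_rank), names(comp_min))
  cluster_id <- id_of_root[as.character(root)]
  out <- data.frame(cluster_id = as.integer(cluster_id),
                    col = cells$col, row = cells$row)
  out <- out[order(out$cluster_id, out$row, out$col), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "year") <- year
  class(out) <- c("cluster_set", "data.frame")
  out
}

#' Number of clusters in a cluster set
#'
#' @param clusters a `cluster_set` from [find_clusters()].
#' @return Integer count.
#' @export
n_clusters <- function(clusters) {
  length(unique(clusters$cluster_id))
}

#' Member cells of one cluster
#'
#' @param clusters a `cluster_set`.
#' @param id cluster id.
#' @return Two-column integer matrix (`col`, `row`).
#' @export
cluster_cells <- function(clusters, id) {
  d <- clusters[clusters$cluster_id == id, c("col", "row"), drop = FALSE]
  as.matrix(d)
}

#' Baseline and follow-up populations inside baseline footprints
#'
#' For each baseline cluster the baseline population is the sum of counts
#' over its member cells at the baseline year, and the follow-up population
#' is the sum over the *same* cell set at the follow-up year.  Splits,
#' merges, and growth beyond the baseline footprint are deliberately
#' ignored: follow-up inhabitants outside every baseline footprint do not
#' count, so summed follow-up populations can fall short of the grid total.
#'
#' @param clusters a `cluster_set` from [find_clusters()] at the baseline
#'   year.
#' @param grid a [population_grid()] holding both years.
#' @param baseline,followup year labels; default to `grid$years`.
#' @return Data frame with columns `cluster_id`, `n_baseline`, `n_followup`.
#' @export
footprint_populations <- function(clusters, grid,
                                  baseline = grid$years[1],
                                  followup = grid$years[2]) {
  base_cells <- populated_cells(grid, baseline)
  key_of <- function(col, row) paste(col, row)
  bkey <- key_of(base_cells$col, base_cells$row)
  ckey <- key_of(clusters$col, clusters$row)
  pos <- match(ckey, bkey)
  if (anyNA(pos)) {
    stop("cluster cell (", clusters$col[which(is.na(pos))[1]], ",",
         clusters$row[which(is.na(pos))[1]],
         ") is not populated in the grid at year ", baseline)
  }
  n_base <- tapply(base_cells$pop[pos], clusters$cluster_id, sum)

  fu <- grid$cells[grid$cells$year == followup, , drop = FALSE]
  fkey <- key_of(fu$col, fu$row)
  fpos <- match(ckey, fkey)
  fu_pop <- ifelse(is.na(fpos), 0L, fu$female[fpos] + fu$male[fpos])
  n_fu <- tapply(fu_pop, clusters$cluster_id, sum)

  ids <- sort(unique(clusters$cluster_id))
  data.frame(cluster_id = ids,
             n_baseline = as.integer(n_base[as.character(ids)]),
             n_followup = as.integer(n_fu[as.character(ids)]))
}

#' Drop clusters below a minimum area
#'
#' Small clusters are dominated by raster discreteness, so the analysis is
#' restricted to clusters of at least `min_cells` cells (default 10).
#'
#' @param clusters a `cluster_set`.
#' @param min_cells minimum member-cell count to keep (>= 1).
#' @return The filtered `cluster_set`, with attributes `n_kept` and
#'   `n_dropped` recording the filter's effect.
#' @export
filter_min_area <- function(clusters, min_cells = 10) {
  if (min_cells < 1) {
    stop("min_cells must be >= 1")
  }
  sizes <- table(clusters$cluster_id)
  keep_ids <- as.integer(names(sizes)[sizes >= min_cells])
  out <- clusters[clusters$cluster_id %in% keep_ids, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "year") <- attr(clusters, "year")
  attr(out, "n_kept") <- length(keep_ids)
  attr(out, "n_dropped") <- length(sizes) - length(keep_ids)
  class(out) <- c("cluster_set", "data.frame")
  out
}

#' Export cluster membership as CSV
#'
#' @param clusters a `cluster_set`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_cluster_csv <- function(clusters, path) {
  d <- as.data.frame(clusters)[, c("cluster_id", "col", "row")]
  utils::write.csv(d, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
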