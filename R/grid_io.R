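#' Construct a population grid
#'
#' A population grid holds per-cell inhabitant counts (female and male
#' separately) for two census years on an integer raster.  Coordinates are
#' 0-based cell indices (`col` east-positive, `row` north-positive); cell
#' centres sit at `(col, row)` and the cell side is the distance unit, so all
#' downstream lengths (perimeter, pairwise distances) are in cell-side units.
#' Unpopulated or water cells are simply absent rows.
#'
#' @param cells data frame with columns `col`, `row`, `year`, `female`,
#'   `male` and optionally `region_id`; one row per cell-year.
#' @param years length-2 vector `(baseline, follow-up)` of year labels.
#'   Defaults to the sorted unique years present in `cells`.
#' @param cell_side_m optional physical cell side in metres (metadata only;
#'   never used in computation).
#'
#' @return An object of class `population_grid`: a list with elements
#'   `cells` (validated data frame), `years`, and `cell_side_m`.
#' @export
population_grid <- function(cells, years = NULL, cell_side_m = NA_real_) {
  stopifnot(is.data.frame(cells))
  required <- c("col", "row", "year", "female", "male")
  missing_cols <- setdiff(required, names(cells))
  if (length(missing_cols) > 0) {
    stop("grid is missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  cells <- as.data.frame(cells)
  for (cc in c("col", "row")) {
    if (any(cells[[cc]] != round(cells[[cc]]))) {
      stop("non-integer grid coordinate in column '", cc, "'")
    }
    cells[[cc]] <- as.integer(cells[[cc]])
  }
  for (cc in c("female", "male")) {
    bad <- which(is.na(cells[[cc]]) | cells[[cc]] < 0 |
                   cells[[cc]] != round(cells[[cc]]))
    if (length(bad) > 0) {
      stop("invalid (negative, missing or non-integer) '", cc,
           "' count at row ", bad[1])
    }
    cells[[cc]] <- as.integer(cells[[cc]])
  }
  key <- paste(cells$col, cells$row, cells$year)
  if (anyDuplicated(key)) {
    stop("duplicate (col,row,year) entry at row ", which(duplicated(key))[1])
  }
  if (is.null(years)) {
    years <- sort(unique(cells$year))
  }
  structure(
    list(cells = cells, years = years, cell_side_m = cell_side_m),
    class = "population_grid"
  )
}

#' @export
print.population_grid <- function(x, ...) {
  cat("population_grid:", nrow(x$cells), "cell-year rows;",
      "years:", paste(x$years, collapse = ", "), "\n")
  for (y in x$years) {
    cat(sprintf("  %s: %d populated cells, %d inhabitants\n",
                y, sum(populated_cells(x, y)$pop >= 1),
                grid_total(x, y)))
  }
  invisible(x)
}

#' Total population of a grid at one year
#'
#' @param grid a [population_grid()].
#' @param year year label.
#' @return Integer total of female + male counts.
#' @export
grid_total <- function(grid, year) {
  d <- grid$cells[grid$cells$year == year, , drop = FALSE]
  as.integer(sum(d$female) + sum(d$male))
}

#' Populated cells of a grid at one year
#'
#' A cell is populated at `year` iff its female + male count is at least 1.
#'
#' @inheritParams grid_total
#' @return Data frame with columns `col`, `row`, `female`, `male`, `pop`.
#' @export
populated_cells <- function(grid, year) {
  d <- grid$cells[grid$cells$year == year, , drop = FALSE]
  d$pop <- d$female + d$male
  d <- d[d$pop >= 1, c("col", "row", "female", "male", "pop"), drop = FALSE]
  rownames(d) <- NULL
  d
}

#' Read a population grid from CSV
#'
#' Expected header: `col,row,year,female,male[,region_id]`, one row per
#' cell-year.  Negative or non-integer counts and duplicated
#' `(col,row,year)` rows are validation errors; a year missing for a cell
#' simply means the cell is unpopulated that year.
#'
#' @param path file path.
#' @param years optional explicit `(baseline, follow-up)` pair.
#' @return A [population_grid()].
#' @export
read_grid_csv <- function(path, years = NULL) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  population_grid(d, years = years)
}

#' Write a population grid to CSV
#'
#' Rows are emitted in a deterministic order (year, then row, then col,
#' ascending) so repeated writes of the same grid are byte-identical.
#'
#' @param grid a [population_grid()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_grid_csv <- function(grid, path) {
  d <- grid$cells
  d <- d[order(d$year, d$row, d$col), , drop = FALSE]
  utils::write.csv(d, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a region-attribute table
#'
#' Regions stand in for the prefecture level of the census: each carries the
#' mean age of its inhabitants and the fraction of tertiary-industry workers,
#' and occupies a rectangular footprint on the grid given by inclusive
#' bounds `col_min..col_max`, `row_min..row_max`.  Region footprints may
#' share a boundary strip one cell wide (ties are resolved to the
#' lexicographically smallest `region_id`), but overlaps of two or more
#' cells in both dimensions are an error.
#'
#' @param path CSV with columns
#'   `region_id,mean_age,tertiary_fraction,col_min,col_max,row_min,row_max`.
#' @return An object of class `region_table`.
#' @export
read_region_table <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  region_table(d)
}

#' Construct a region-attribute table
#'
#' @param regions data frame as documented in [read_region_table()].
#' @return An object of class `region_table`.
#' @export
region_table <- function(regions) {
  required <- c("region_id", "mean_age", "tertiary_fraction",
                "col_min", "col_max", "row_min", "row_max")
  missing_cols <- setdiff(required, names(regions))
  if (length(missing_cols) > 0) {
    stop("region table is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  regions <- as.data.frame(regions)
  regions$region_id <- as.character(regions$region_id)
  if (anyDuplicated(regions$region_id)) {
    stop("duplicate region_id: ",
         regions$region_id[duplicated(regions$region_id)][1])
  }
  bad <- which(regions$tertiary_fraction < 0 | regions$tertiary_fraction > 1)
  if (length(bad) > 0) {
    stop("tertiary_fraction outside [0,1] for region ",
         regions$region_id[bad[1]])
  }
  if (any(regions$col_min > regions$col_max) ||
      any(regions$row_min > regions$row_max)) {
    stop("degenerate region bounding box (min > max)")
  }
  n <- nrow(regions)
  if (n > 1) {
    for (i in seq_len(n - 1)) {
      for (j in seq(i + 1, n)) {
        ow <- min(regions$col_max[i], regions$col_max[j]) -
          max(regions$col_min[i], regions$col_min[j]) + 1
        oh <- min(regions$row_max[i], regions$row_max[j]) -
          max(regions$row_min[i], regions$row_min[j]) + 1
        # a shared strip one cell wide is a legal boundary (tie rule);
        # a two-dimensional patch in common is a table error
        if (ow >= 2 && oh >= 2) {
          stop("regions ", regions$region_id[i], " and ",
               regions$region_id[j], " overlap")
        }
      }
    }
  }
  structure(list(regions = regions), class = "region_table")
}

#' @export
print.region_table <- function(x, ...) {
  cat("region_table:", nrow(x$regions), "regions\n")
  invisible(x)
}

#' Look up the region containing a coordinate
#'
#' The coordinate may be fractional (cluster representative cells can be
#' averaged positions).  A point inside exactly one region footprint gets
#' that region; a point on a shared edge is assigned to the
#' lexicographically smallest `region_id`; a point outside all regions
#' returns `NA`.
#'
#' @param table a [region_table()].
#' @param col,row coordinate (possibly fractional, cell units).
#' @return `region_id` as a character scalar, or `NA_character_`.
#' @export
region_lookup <- function(table, col, row) {
  r <- table$regions
  # inclusive cell bounds; half a cell of slack so fractional positions on
  # the rim of a footprint still fall inside it
  hit <- which(col >= r$col_min - 0.5 & col <= r$col_max + 0.5 &
                 row >= r$row_min - 0.5 & row <= r$row_max + 0.5)
  if (length(hit) == 0) {
    return(NA_character_)
  }
  sort(r$region_id[hit])[1]
}

#' Write a region table to CSV
#'
#' @param table a [region_table()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_region_table <- function(table, path) {
  d <- table$regions[order(table$regions$region_id), , drop = FALSE]
  utils::write.csv(d, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Percent change between two totals
#'
#' @param before,after totals at the two time points.
#' @param digits decimal places to round to (default 2).
#' @return Percent change `100 * (after - before) / before`, rounded.
#' @export
percent_change <- function(before, after, digits = 2) {
  round(100 * (after - before) / before, digits)
}
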