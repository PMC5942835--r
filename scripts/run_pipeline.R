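#!/usr/bin/env Rscript

# Thin command-line wrapper over popclust::run_pipeline().
#
# Either analyse real inputs:
#   Rscript scripts/run_pipeline.R --grid grid.csv --regions regions.csv \
#     --baseline-year 2005 --followup-year 2010 --out out/
# or simulate first:
#   Rscript scripts/run_pipeline.R --simulate --n-clusters 200 --seed 7 \
#     --out out/

suppressPackageStartupMessages({
  library(optparse)
  library(popclust)
})

opts <- parse_args(OptionParser(option_list = list(
  make_option("--grid", type = "character", default = NULL),
  make_option("--regions", type = "character", default = NULL),
  make_option("--simulate", action = "store_true", default = FALSE),
  make_option("--n-clusters", type = "integer", default = 100,
              dest = "n_clusters"),
  make_option("--baseline-year", type = "character", default = NULL,
              dest = "baseline"),
  make_option("--followup-year", type = "character", default = NULL,
              dest = "followup"),
  make_option("--min-cells", type = "integer", default = 10,
              dest = "min_cells"),
  make_option("--seed", type = "integer", default = 1),
  make_option("--out", type = "character", default = "popclust-report"),
  make_option("--no-selection", action = "store_true", default = FALSE,
              dest = "no_selection"),
  make_option("--quiet", action = "store_true", default = FALSE)
)))

if (opts$simulate) {
  run_pipeline(
    synthetic = synthetic_config(n_clusters = opts$n_clusters,
                                 seed = opts$seed),
    min_cells = opts$min_cells,
    selection = !opts$no_selection,
    out_dir = opts$out,
    verbose = !opts$quiet
  )
} else {
  if (is.null(opts$grid) || is.null(opts$regions)) {
    stop("give --grid and --regions, or --simulate")
  }
  baseline <- opts$baseline
  followup <- opts$followup
  if (!is.null(baseline) && !is.na(suppressWarnings(as.numeric(baseline)))) {
    baseline <- as.numeric(baseline)
  }
  if (!is.null(followup) && !is.na(suppressWarnings(as.numeric(followup)))) {
    followup <- as.numeric(followup)
  }
  run_pipeline(
    grid = read_grid_csv(opts$grid),
    regions = read_region_table(opts$regions),
    baseline = baseline, followup = followup,
    min_cells = opts$min_cells,
    selection = !opts$no_selection,
    out_dir = opts$out,
    verbose = !opts$quiet
  )
}
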