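#' Run the full cluster-growth analysis pipeline
#'
#' Orchestrates cluster detection, the minimum-area filter, feature
#' construction, descriptive statistics, correlation and VIF diagnostics,
#' the Poisson fit with overdispersion test, the negative binomial
#' multivariate and univariate fits, optional backward-AIC selection over
#' interactions, and the size-growth regression.  Inputs are either a grid
#' and region table (real data) or a [synthetic_config()] (simulation);
#' exactly one must be given.  All outputs are written as plain CSV/JSON
#' under `out_dir` together with a manifest recording the configuration, so
#' a bundle can be reproduced bit-for-bit.
#'
#' @param grid a [population_grid()], or `NULL` when simulating.
#' @param regions a [region_table()], or `NULL` when simulating.
#' @param synthetic a [synthetic_config()], or `NULL` with real inputs.
#' @param baseline,followup year labels (default: the grid's year pair).
#' @param min_cells minimum cluster area kept (default 10).
#' @param center mean-centre covariates in the multivariate fit.
#' @param selection run backward-AIC selection (the slow stage).
#' @param out_dir output directory, or `NULL` to skip writing files.
#' @param verbose print stage progress.
#' @return Invisibly, a list with every stage result: `clusters`,
#'   `features`, `summary`, `correlations`, `vif`, `poisson`,
#'   `overdispersion`, `negbin`, `univariate`, `selection`, `size_growth`,
#'   `counts`, `manifest`.
#' @export
run_pipeline <- function(grid = NULL, regions = NULL, synthetic = NULL,
                         baseline = NULL, followup = NULL,
                         min_cells = 10, center = TRUE, selection = FALSE,
                         out_dir = NULL, verbose = FALSE) {
  if (is.null(synthetic) == (is.null(grid) || is.null(regions))) {
    stop("give either (grid, regions) or a synthetic config, not both")
  }
  say <- function(...) if (verbose) message(...)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "': ", conditionMessage(e),
           call. = FALSE)
    })
  }
  truth <- NULL
  if (!is.null(synthetic)) {
    say("simulate: generating synthetic grid (seed ", synthetic$seed, ")")
    ds <- stage("simulate", generate_dataset(synthetic))
    grid <- ds$grid
    regions <- ds$regions
    truth <- ds$truth
  }
  if (is.null(baseline)) baseline <- grid$years[1]
  if (is.null(followup)) followup <- grid$years[2]

  say("cluster: city clustering at year ", baseline)
  clusters <- find_clusters(grid, baseline)
  n_all <- n_clusters(clusters)
  clusters <- filter_min_area(clusters, min_cells)
  n_kept <- attr(clusters, "n_kept")
  say("cluster: ", n_all, " clusters, ", n_kept,
      " with at least ", min_cells, " cells")
  if (n_kept == 0) {
    stop("pipeline stage 'cluster': no cluster passes the min-area filter")
  }

  say("featurize: ", n_kept, " clusters")
  features <- stage("featurize",
                    build_feature_table(clusters, grid, regions,
                                        baseline = baseline,
                                        followup = followup))

  summary_tab <- summarize_features(features)
  correlations <- lapply(
    stats::setNames(nm = c("pearson", "spearman", "kendall")),
    function(m) correlation_matrix(features, m)
  )
  vifs <- stage("diagnostics", vif(features))

  say("fit: Poisson + overdispersion test")
  mm <- build_model_matrix(features, center = center)
  pois <- stage("fit", fit_poisson_offset(mm))
  od <- overdispersion_test(pois, response = mm$response)
  say(sprintf("fit: overdispersion T = %.2f (p = %.3g)",
              od$statistic, od$p_value))

  nb <- NULL
  univ <- NULL
  if (od$overdispersed) {
    say("fit: negative binomial (overdispersion established)")
    nb <- stage("fit", fit_negbin_offset(mm))
    univ <- fit_univariate_suite(features)
  } else {
    say("fit: no overdispersion; keeping the Poisson model")
  }

  sel <- NULL
  if (selection) {
    say("select: backward AIC over mains + pairwise interactions")
    sel <- stage("select", backward_aic_selection(features))
  }

  sg <- size_growth_regression(features)

  counts <- list(clusters_total = n_all, clusters_kept = n_kept,
                 clusters_dropped = n_all - n_kept,
                 grid_total_baseline = grid_total(grid, baseline),
                 grid_total_followup = grid_total(grid, followup))
  manifest <- list(
    package = "popclust",
    version = as.character(utils::packageVersion("popclust")),
    baseline = baseline, followup = followup,
    min_cells = min_cells, center = center, selection = selection,
    synthetic_seed = if (!is.null(synthetic)) synthetic$seed else NULL,
    counts = counts
  )

  result <- list(clusters = clusters, features = features,
                 summary = summary_tab, correlations = correlations,
                 vif = vifs, poisson = pois, overdispersion = od,
                 negbin = nb, univariate = univ, selection = sel,
                 size_growth = sg, counts = counts, manifest = manifest,
                 truth = truth)
  if (!is.null(out_dir)) {
    write_report_bundle(result, out_dir)
  }
  invisible(result)
}

fit_report <- function(fit) {
  if (is.null(fit)) return(NULL)
  list(family = fit$family,
       coefficients = as.list(fit$coefficients),
       se = as.list(fit$se),
       ci95 = apply(fit$ci95, 1, as.list),
       theta = fit$theta,
       loglik = fit$loglik,
       aic = fit$aic)
}

#' Write a pipeline result as a report bundle
#'
#' Emits the feature table, descriptive summary, correlation and VIF tables
#' as CSV; fits, overdispersion test, selection trace, size-growth
#' regression, and the manifest as JSON.
#'
#' @param result a [run_pipeline()] result.
#' @param out_dir output directory (created if absent).
#' @return `out_dir`, invisibly.
#' @export
write_report_bundle <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  path <- function(f) file.path(out_dir, f)
  write_feature_csv(result$features, path("features.csv"))
  utils::write.csv(result$summary, path("summary.csv"), row.names = FALSE)
  for (m in names(result$correlations)) {
    utils::write.csv(result$correlations[[m]],
                     path(paste0("correlation_", m, ".csv")))
  }
  utils::write.csv(data.frame(covariate = names(result$vif),
                              vif = unname(result$vif)),
                   path("vif.csv"), row.names = FALSE)
  jwrite <- function(x, f) {
    jsonlite::write_json(x, path(f), auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, null = "null")
  }
  jwrite(fit_report(result$poisson), "fit_poisson.json")
  jwrite(result$overdispersion, "overdispersion.json")
  if (!is.null(result$negbin)) jwrite(fit_report(result$negbin),
                                      "fit_negbin.json")
  if (!is.null(result$univariate)) {
    jwrite(lapply(result$univariate, function(f) {
      if (inherits(f, "error")) list(error = conditionMessage(f))
      else fit_report(f)
    }), "fit_univariate.json")
  }
  if (!is.null(result$selection)) {
    jwrite(list(terms = result$selection$terms,
                trace = result$selection$trace,
                final = fit_report(result$selection$final)),
           "selection.json")
  }
  jwrite(result$size_growth, "size_growth.json")
  jwrite(result$manifest, "manifest.json")
  invisible(out_dir)
}
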