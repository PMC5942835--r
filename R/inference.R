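#' Build the regression model matrix
#'
#' Response is the follow-up footprint population; the offset is
#' `log(n_baseline)` with its coefficient fixed at 1, so the model describes
#' relative five-year growth.  Area and Density are log-transformed (both
#' are heavy-tailed); the remaining covariates — roundness, irregularity,
#' characteristic length, heterogeneity, gender, age, tertiary — enter
#' untransformed.  With `center = TRUE` every covariate is mean-centred,
#' which is required before forming pairwise interaction terms so that
#' interactions do not inflate VIFs.
#'
#' @param features feature table from [build_feature_table()].
#' @param center mean-centre the covariate columns?
#' @return An object of class `model_matrix`: list with `response`,
#'   `offset`, covariate matrix `X` (columns `log_area`, `log_density`,
#'   `roundness`, `irregularity`, `cl`, `heterogeneity`, `gender`, `age`,
#'   `tertiary`), `centered` flag, and the column means removed.
#' @export
build_model_matrix <- function(features, center = FALSE) {
  if (any(features$density <= 0)) {
    stop("non-positive density; cannot log-transform")
  }
  if (any(features$S < 1)) {
    stop("cluster area below 1")
  }
  X <- cbind(
    log_area = log(features$S),
    log_density = log(features$density),
    roundness = features$roundness,
    irregularity = features$irregularity,
    cl = features$cl,
    heterogeneity = features$heterogeneity,
    gender = features$gender,
    age = features$age,
    tertiary = features$tertiary
  )
  if (any(!is.finite(X))) {
    stop("non-finite covariate value in feature table")
  }
  means <- rep(0, ncol(X))
  names(means) <- colnames(X)
  if (center) {
    means <- colMeans(X)
    X <- sweep(X, 2, means)
  }
  structure(
    list(response = features$n_followup,
         offset = log(features$n_baseline),
         X = X,
         centered = center,
         means = means,
         cluster_id = features$cluster_id),
    class = "model_matrix"
  )
}

#' @export
print.model_matrix <- function(x, ...) {
  cat("model_matrix:", length(x$response), "clusters,",
      ncol(x$X), "covariates",
      if (x$centered) "(centred)" else "(uncentred)", "\n")
  invisible(x)
}

fit_result <- function(family, fit, theta = NULL, theta_capped = FALSE) {
  beta <- stats::coef(fit)
  se <- sqrt(diag(stats::vcov(fit)))
  ll <- as.numeric(stats::logLik(fit))
  k <- length(beta) + if (identical(family, "negbin")) 1 else 0
  structure(
    list(family = family,
         coefficients = beta,
         theta = theta,
         se = se,
         ci95 = cbind(lower = beta - 1.96 * se, upper = beta + 1.96 * se),
         loglik = ll,
         aic = 2 * k - 2 * ll,
         fitted = stats::fitted(fit),
         theta_capped = theta_capped,
         model = fit),
    class = "popclust_fit"
  )
}

#' @export
print.popclust_fit <- function(x, ...) {
  cat(sprintf("%s regression with log-baseline offset (N = %d)\n",
              if (x$family == "negbin") "Negative binomial" else "Poisson",
              length(x$fitted)))
  tab <- data.frame(estimate = x$coefficients, se = x$se,
                    ci_lower = x$ci95[, "lower"], ci_upper = x$ci95[, "upper"])
  print(round(tab, 4))
  if (!is.null(x$theta)) cat(sprintf("theta = %.4g\n", x$theta))
  cat(sprintf("logLik = %.2f, AIC = %.2f\n", x$loglik, x$aic))
  invisible(x)
}

#' Poisson regression with log-baseline offset
#'
#' Maximum-likelihood Poisson fit of the follow-up counts with log link,
#' the model-matrix covariates, and `log(n_baseline)` as a unit-coefficient
#' offset.
#'
#' @param mm a [build_model_matrix()] object.
#' @return A `popclust_fit` (family `"poisson"`).
#' @export
fit_poisson_offset <- function(mm) {
  df <- data.frame(y = mm$response, mm$X, check.names = FALSE)
  off <- mm$offset
  fml <- if (ncol(mm$X) > 0) {
    stats::reformulate(colnames(mm$X), response = "y")
  } else {
    y ~ 1
  }
  fit <- stats::glm(fml, family = stats::poisson(), data = df, offset = off,
                    control = stats::glm.control(epsilon = 1e-10, maxit = 100))
  if (!fit$converged) {
    stop("Poisson IRLS failed to converge after ", fit$iter, " iterations")
  }
  fit_result("poisson", fit)
}

#' Overdispersion score test for a Poisson fit
#'
#' Dean–Lawless score statistic
#' `T = sum((y - mu)^2 - y) / sqrt(2 * sum(mu^2))`,
#' which is asymptotically standard normal when the Poisson model holds.
#' The test is one-sided against the overdispersed (upper) alternative;
#' rejection motivates the negative binomial model.
#'
#' @param poisson_fit a `popclust_fit` of family `"poisson"`.
#' @param response observed counts (defaults to those used in the fit).
#' @param level significance level for the reported decision.
#' @return List with `statistic`, `p_value`, `overdispersed`, `level`.
#' @export
overdispersion_test <- function(poisson_fit,
                                response = poisson_fit$model$y,
                                level = 0.001) {
  mu <- poisson_fit$fitted
  if (length(mu) < 2) {
    stop("overdispersion test needs at least 2 clusters")
  }
  statistic <- sum((response - mu)^2 - response) / sqrt(2 * sum(mu^2))
  p <- stats::pnorm(statistic, lower.tail = FALSE)
  list(statistic = statistic, p_value = p,
       overdispersed = p < level, level = level)
}

#' Negative binomial regression with log-baseline offset
#'
#' NB2 model: the follow-up count is negative binomial with mean
#' `mu_c = n_baseline * exp(b0 + sum b_i X_i)` and variance
#' `mu_c + mu_c^2 / theta`, with a single dispersion `theta` shared by all
#' clusters.  Fitted by alternating IRLS for the coefficients and ML for
#' `theta` (`MASS::glm.nb`) to a log-likelihood tolerance of 1e-8.  When the
#' data are Poisson-like `theta` diverges; it is then capped at `theta_max`
#' and flagged.
#'
#' @param mm a [build_model_matrix()] object.
#' @param theta_max cap on the dispersion estimate.
#' @return A `popclust_fit` (family `"negbin"`) with `theta`.
#' @export
fit_negbin_offset <- function(mm, theta_max = 1e6) {
  df <- data.frame(y = mm$response, mm$X, check.names = FALSE)
  df$.off <- mm$offset
  fml <- if (ncol(mm$X) > 0) {
    stats::as.formula(paste("y ~", paste(colnames(mm$X), collapse = " + "),
                            "+ offset(.off)"))
  } else {
    y ~ 1 + offset(.off)
  }
  capped <- FALSE
  fit <- withCallingHandlers(
    MASS::glm.nb(fml, data = df,
                 control = stats::glm.control(epsilon = 1e-8, maxit = 50)),
    warning = function(w) {
      if (grepl("iteration limit|theta", conditionMessage(w))) {
        capped <<- TRUE
        invokeRestart("muffleWarning")
      }
    }
  )
  theta <- as.numeric(fit$theta)
  if (theta > theta_max) {
    theta <- theta_max
    capped <- TRUE
  }
  fit_result("negbin", fit, theta = theta, theta_capped = capped)
}

#' Univariate negative binomial fits, one per covariate
#'
#' Fits each covariate alone (with the same log-baseline offset as the
#' multivariate model).  Per-covariate failures are reported and do not stop
#' the remaining fits.
#'
#' @param features feature table from [build_feature_table()].
#' @return Named list of `popclust_fit` objects (failed fits carry the
#'   error condition instead).
#' @export
fit_univariate_suite <- function(features) {
  mm <- build_model_matrix(features)
  out <- list()
  for (j in colnames(mm$X)) {
    sub <- mm
    sub$X <- mm$X[, j, drop = FALSE]
    out[[j]] <- tryCatch(fit_negbin_offset(sub), error = function(e) e)
  }
  out
}

#' Interpret a regression coefficient as an effect size
#'
#' For an untransformed covariate, an increase of `delta` units multiplies
#' the expected follow-up count by `exp(beta * delta)`
#' (`kind = "multiplicative"`); the associated fractional decrease is
#' `1 - exp(beta * delta)` (`kind = "decrease_fraction"`).  For the logged
#' covariates (Area, Density) the coefficient is directly an elasticity:
#' a 1% covariate increase gives a `beta` percent response change
#' (`kind = "elasticity"`).
#'
#' @param beta coefficient.
#' @param delta covariate increase (ignored for `"elasticity"`).
#' @param kind one of `"multiplicative"`, `"decrease_fraction"`,
#'   `"elasticity"`.
#' @return Effect size as a number.
#' @export
effect_transform <- function(beta, delta = 1,
                             kind = c("multiplicative", "decrease_fraction",
                                      "elasticity")) {
  kind <- match.arg(kind)
  switch(kind,
         multiplicative = exp(beta * delta),
         decrease_fraction = 1 - exp(beta * delta),
         elasticity = beta)
}

#' Correlation matrix between the model covariates
#'
#' @param features feature table.
#' @param method `"pearson"`, `"spearman"`, or `"kendall"` (tau-b,
#'   tie-corrected).
#' @return Symmetric correlation matrix over the nine covariates; entries
#'   for constant columns are `NA`.
#' @export
correlation_matrix <- function(features,
                               method = c("pearson", "spearman", "kendall")) {
  method <- match.arg(method)
  X <- build_model_matrix(features)$X
  constant <- apply(X, 2, function(v) stats::sd(v) == 0)
  out <- suppressWarnings(stats::cor(X, method = method))
  out[constant, ] <- NA
  out[, constant] <- NA
  diag(out) <- ifelse(constant, NA, 1)
  out
}

#' Variance inflation factors of the model covariates
#'
#' `VIF_j = 1 / (1 - R^2_j)` where `R^2_j` comes from regressing covariate j
#' on all the others.  Values above 10 (and arguably 5) signal collinearity
#' that undermines a multivariate fit.  Perfectly collinear covariates give
#' `Inf`.
#'
#' @param features feature table.
#' @return Named numeric vector of VIFs.
#' @export
vif <- function(features) {
  X <- build_model_matrix(features)$X
  p <- ncol(X)
  if (p < 2) stop("VIF needs at least 2 covariates")
  if (nrow(X) <= p) stop("VIF needs more clusters than covariates")
  out <- numeric(p)
  names(out) <- colnames(X)
  for (j in seq_len(p)) {
    fit <- stats::lm.fit(cbind(1, X[, -j, drop = FALSE]), X[, j])
    r2 <- 1 - sum(fit$residuals^2) / sum((X[, j] - mean(X[, j]))^2)
    out[j] <- if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }
  out
}

# -- backward AIC selection over mains + pairwise interactions --------------

# design columns for a term set: mains are (centred) covariates, an
# interaction "a:b" is the product of the centred columns (not re-centred)
selection_design <- function(X, terms) {
  cols <- lapply(terms, function(tm) {
    parts <- strsplit(tm, ":", fixed = TRUE)[[1]]
    if (length(parts) == 1) X[, parts] else X[, parts[1]] * X[, parts[2]]
  })
  out <- do.call(cbind, cols)
  colnames(out) <- terms
  out
}

nb_loglik <- function(y, mu, theta) {
  sum(stats::dnbinom(y, size = theta, mu = mu, log = TRUE))
}

# fixed-theta NB fit used to rank candidate deletions quickly
nb_fixed_theta_fit <- function(y, Xd, off, theta, start = NULL) {
  fam <- MASS::negative.binomial(theta)
  dat <- data.frame(y = y, Xd, check.names = FALSE)
  fml <- if (ncol(Xd) > 0) {
    stats::reformulate(paste0("`", colnames(Xd), "`"), response = "y")
  } else {
    y ~ 1
  }
  fit <- suppressWarnings(
    stats::glm(fml, family = fam, data = dat, offset = off)
  )
  list(fit = fit, loglik = nb_loglik(y, stats::fitted(fit), theta))
}

full_ml_fit <- function(mm, terms) {
  sub <- mm
  sub$X <- if (length(terms) > 0) {
    selection_design(mm$X, terms)
  } else {
    mm$X[, integer(0), drop = FALSE]
  }
  fit_negbin_offset(sub)
}

#' Backward AIC selection over main effects and pairwise interactions
#'
#' Starts from all nine main effects plus all 36 pairwise interaction terms
#' (formed from the mean-centred covariates; centring keeps the interaction
#' VIFs down) and repeatedly removes the single term whose deletion most
#' decreases the AIC, stopping when no deletion decreases it.  Marginality
#' is respected: a main effect cannot leave while any interaction involving
#' it remains.  Candidate deletions within a step are ranked with the
#' dispersion held at the current model's estimate; the chosen model is then
#' refit by full ML (theta re-estimated) and the step is accepted only if
#' the full-ML AIC decreased.
#'
#' @param features feature table.
#' @param include_interactions start from mains + pairwise interactions
#'   (default) or mains only.
#' @return List with `final` (a `popclust_fit`), `terms` (retained term
#'   labels), and `trace` (data frame of accepted steps: dropped term and
#'   AIC, non-increasing).
#' @export
backward_aic_selection <- function(features, include_interactions = TRUE) {
  mm <- build_model_matrix(features, center = TRUE)
  mains <- colnames(mm$X)
  terms <- mains
  if (include_interactions) {
    pairs <- utils::combn(mains, 2)
    terms <- c(mains, apply(pairs, 2, paste, collapse = ":"))
  }
  current <- full_ml_fit(mm, terms)
  trace <- data.frame(dropped = "<start>", aic = current$aic,
                      stringsAsFactors = FALSE)
  y <- mm$response
  off <- mm$offset
  repeat {
    inter <- terms[grepl(":", terms, fixed = TRUE)]
    in_inter <- unique(unlist(strsplit(inter, ":", fixed = TRUE)))
    removable <- c(inter, setdiff(setdiff(terms, inter), in_inter))
    if (length(removable) == 0) break
    theta <- current$theta
    # rank deletions at fixed theta
    cand_ll <- vapply(removable, function(tm) {
      keep <- setdiff(terms, tm)
      Xd <- selection_design(mm$X, keep)
      res <- tryCatch(nb_fixed_theta_fit(y, Xd, off, theta),
                      error = function(e) NULL)
      if (is.null(res)) -Inf else res$loglik
    }, numeric(1))
    if (all(!is.finite(cand_ll))) break
    best_term <- removable[which.max(cand_ll)]
    candidate <- tryCatch(full_ml_fit(mm, setdiff(terms, best_term)),
                          error = function(e) NULL)
    if (is.null(candidate)) {
      warning("refit after dropping ", best_term, " failed; stopping")
      break
    }
    if (candidate$aic < current$aic) {
      terms <- setdiff(terms, best_term)
      current <- candidate
      trace <- rbind(trace, data.frame(dropped = best_term,
                                       aic = current$aic,
                                       stringsAsFactors = FALSE))
    } else {
      break
    }
  }
  list(final = current, terms = terms, trace = trace)
}

#' Regression of log growth on log baseline size
#'
#' Fits `log(n_followup / n_baseline) = beta * log(n_baseline)` by ordinary
#' least squares through the origin (no intercept), quantifying whether
#' larger clusters grow faster.  Clusters with zero follow-up population are
#' excluded (their count is reported).
#'
#' @param growth data frame with `n_baseline`, `n_followup` (e.g. from
#'   [footprint_populations()] or a feature table).
#' @return List with `slope`, `se`, `p_value`, `n_used`, `n_excluded`.
#' @export
size_growth_regression <- function(growth) {
  keep <- growth$n_followup >= 1 & growth$n_baseline >= 1
  d <- growth[keep, , drop = FALSE]
  y <- log(d$n_followup / d$n_baseline)
  x <- log(d$n_baseline)
  fit <- stats::lm(y ~ 0 + x)
  sm <- summary(fit)
  list(slope = unname(stats::coef(fit)["x"]),
       se = sm$coefficients["x", "Std. Error"],
       p_value = sm$coefficients["x", "Pr(>|t|)"],
       n_used = nrow(d),
       n_excluded = sum(!keep))
}

#' Descriptive statistics of the feature table
#'
#' Per-variable minimum, maximum, median, mean, sample SD, coefficient of
#' variation (SD/mean), and adjusted Fisher–Pearson sample skewness, for the
#' response, offset source, and all covariates (logged and raw Area and
#' Density both shown).
#'
#' @param features feature table.
#' @return Data frame, one row per variable.
#' @export
summarize_features <- function(features) {
  X <- build_model_matrix(features)$X
  vars <- cbind(
    n_followup = features$n_followup,
    n_baseline = features$n_baseline,
    X,
    area = features$S,
    density = features$density
  )
  one <- function(v) {
    m <- mean(v)
    s <- stats::sd(v)
    n <- length(v)
    skew <- if (s == 0 || n < 3) {
      0
    } else {
      g1 <- mean((v - m)^3) / (mean((v - m)^2))^1.5
      g1 * sqrt(n * (n - 1)) / (n - 2)
    }
    c(min = min(v), max = max(v), median = stats::median(v), mean = m,
      sd = s, cv = if (m == 0) NA_real_ else s / m, skewness = skew)
  }
  out <- t(apply(vars, 2, one))
  data.frame(variable = rownames(out), out, row.names = NULL)
}
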