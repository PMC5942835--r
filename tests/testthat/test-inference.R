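test_that("model matrix logs Area and Density only, centres on request", {
  feats <- small_features(n_clusters = 40, seed = 3)
  mm <- build_model_matrix(feats)
  expect_equal(mm$X[, "log_area"], log(feats$S))
  expect_equal(mm$X[, "log_density"], log(feats$density))
  expect_equal(mm$X[, "roundness"], feats$roundness)
  expect_equal(mm$response, feats$n_followup)
  expect_equal(mm$offset, log(feats$n_baseline))
  # the min-area filter at 10 cells maps to a log(Area) floor of 2.303
  expect_gte(min(mm$X[, "log_area"]), log(10))
  expect_equal(round(log(10), 3), 2.303)

  mmc <- build_model_matrix(feats, center = TRUE)
  expect_true(all(abs(colMeans(mmc$X)) < 1e-12))

  feats$density[1] <- 0
  expect_error(build_model_matrix(feats), "density")
})

test_that("Poisson offset fit: exact mean match gives a zero intercept", {
  n_base <- c(10L, 40L, 160L, 640L)
  mm <- raw_mm(response = n_base, offset = log(n_base))
  fit <- fit_poisson_offset(mm)
  expect_equal(unname(fit$coefficients["(Intercept)"]), 0, tolerance = 1e-8)

  # doubling the baseline (offset) with the same response halves exp(b0)
  mm2 <- raw_mm(response = n_base, offset = log(2 * n_base))
  fit2 <- fit_poisson_offset(mm2)
  expect_equal(exp(unname(fit2$coefficients["(Intercept)"])), 0.5,
               tolerance = 1e-8)
})

test_that("offset contract: scaling baselines shifts only the intercept", {
  feats <- small_features(n_clusters = 80, seed = 8)
  mm <- build_model_matrix(feats)
  for (fit_fun in list(fit_poisson_offset, fit_negbin_offset)) {
    f1 <- fit_fun(mm)
    mm_k <- mm
    mm_k$offset <- mm$offset + log(7)
    f2 <- fit_fun(mm_k)
    expect_equal(unname(f2$coefficients["(Intercept)"]),
                 unname(f1$coefficients["(Intercept)"]) - log(7),
                 tolerance = 1e-6)
    expect_equal(f2$coefficients[-1], f1$coefficients[-1],
                 tolerance = 1e-6)
  }
})

test_that("Poisson simulation recovers known coefficients within 3 SE", {
  set.seed(501)
  n <- 500
  X <- cbind(x1 = rnorm(n), x2 = rnorm(n), x3 = rnorm(n))
  beta <- c(0.05, 0.10, -0.08, 0.03)
  off <- log(sample(50:500, n, replace = TRUE))
  mu <- exp(off + beta[1] + X %*% beta[-1])
  mm <- raw_mm(response = rpois(n, mu), offset = off, X = X)
  fit <- fit_poisson_offset(mm)
  expect_true(all(abs(fit$coefficients - beta) <= 3 * fit$se))
})

test_that("overdispersion statistic matches the score formula", {
  # y = mu = 1 everywhere: each term contributes (0 - 1), so
  # T = -N / sqrt(2 N); at N = 2 that is -1
  fake <- structure(list(fitted = c(1, 1), model = list(y = c(1, 1))),
                    class = "popclust_fit")
  od <- overdispersion_test(fake)
  expect_equal(od$statistic, -2 / sqrt(2 * 2))
  expect_false(od$overdispersed)

  # hand-computed mixed case
  y <- c(3, 0, 5)
  mu <- c(2, 1, 4)
  fake2 <- structure(list(fitted = mu, model = list(y = y)),
                     class = "popclust_fit")
  by_hand <- ((3 - 2)^2 - 3 + (0 - 1)^2 - 0 + (5 - 4)^2 - 5) /
    sqrt(2 * (4 + 1 + 16))
  expect_equal(overdispersion_test(fake2)$statistic, by_hand)

  single <- structure(list(fitted = 1, model = list(y = 1)),
                      class = "popclust_fit")
  expect_error(overdispersion_test(single), "at least 2")
})

test_that("overdispersed data yield a large positive statistic, Poisson-like data do not", {
  set.seed(77)
  n <- 500
  off <- log(sample(100:1000, n, replace = TRUE))
  mu <- exp(off)
  y_nb <- rnbinom(n, size = 1, mu = mu)
  fit_nb_data <- fit_poisson_offset(raw_mm(y_nb, off))
  od <- overdispersion_test(fit_nb_data)
  expect_gt(od$statistic, 10)
  expect_lt(od$p_value, 0.001)

  y_pois <- rpois(n, mu)
  od2 <- overdispersion_test(fit_poisson_offset(raw_mm(y_pois, off)))
  expect_lt(abs(od2$statistic), 4)
})

test_that("negative binomial fit recovers beta and theta on simulated data", {
  set.seed(901)
  n <- 2000
  X <- cbind(x1 = rnorm(n), x2 = rnorm(n))
  beta <- c(0.02, 0.08, -0.05)
  theta <- 5
  off <- log(sample(50:2000, n, replace = TRUE))
  mu <- exp(off + beta[1] + X %*% beta[-1])
  y <- rnbinom(n, size = theta, mu = mu)
  fit <- fit_negbin_offset(raw_mm(y, off, X))
  expect_true(all(abs(fit$coefficients - beta) <= 3 * fit$se))
  expect_lt(abs(fit$theta - theta) / theta, 0.2)
  expect_equal(fit$aic, 2 * (length(beta) + 1) - 2 * fit$loglik)
})

test_that("on Poisson data the NB fit caps theta and matches Poisson coefficients", {
  set.seed(19)
  n <- 400
  X <- cbind(x1 = rnorm(n))
  off <- log(sample(100:500, n, replace = TRUE))
  mu <- exp(off + 0.02 + 0.05 * X[, 1])
  y <- rpois(n, mu)
  mm <- raw_mm(y, off, X)
  pois <- fit_poisson_offset(mm)
  nb <- fit_negbin_offset(mm, theta_max = 1e6)
  expect_true(nb$theta_capped || nb$theta > 1e4)
  expect_equal(unname(nb$coefficients), unname(pois$coefficients),
               tolerance = 1e-4)
})

test_that("univariate suite fits each covariate with the shared offset", {
  feats <- small_features(n_clusters = 60, seed = 14)
  suite <- fit_univariate_suite(feats)
  expect_length(suite, 9)
  expect_named(suite, c("log_area", "log_density", "roundness",
                        "irregularity", "cl", "heterogeneity", "gender",
                        "age", "tertiary"))
  for (f in suite) {
    expect_s3_class(f, "popclust_fit")
    expect_length(f$coefficients, 2)
  }
})

test_that("effect transforms reproduce the printed effect sizes", {
  expect_equal(signif(effect_transform(-0.0327, 0.01, "decrease_fraction"), 3),
               3.27e-4)
  expect_equal(signif(effect_transform(-0.0024, 0.01, "decrease_fraction"), 3),
               2.40e-5)
  expect_equal(effect_transform(0, 5, "multiplicative"), 1)
  expect_equal(effect_transform(0, 5, "decrease_fraction"), 0)
  expect_equal(effect_transform(0.021, kind = "elasticity"), 0.021)
})

test_that("correlation matrix is symmetric with exact tau on a known set", {
  X <- orthonormal_X(40)
  feats <- features_from_X(X)
  feats$roundness <- c(1, 2, 3, 4, 5, rep(6, 35))
  feats$cl <- c(2, 1, 3, 5, 4, rep(6, 35))
  for (m in c("pearson", "spearman", "kendall")) {
    cm <- correlation_matrix(feats, m)
    expect_equal(cm, t(cm))
    expect_equal(unname(diag(cm)), rep(1, 9))
  }
  ck <- correlation_matrix(feats, "kendall")
  expect_equal(ck["roundness", "cl"],
               oracle_kendall(feats$roundness, feats$cl))

  # monotone transform: rank correlations hit 1, Pearson stays below
  feats2 <- features_from_X(orthonormal_X(30, seed = 9))
  x <- seq(-2, 2, length.out = 30)
  feats2$roundness <- x
  feats2$cl <- x^3
  expect_equal(correlation_matrix(feats2, "spearman")["roundness", "cl"], 1)
  expect_equal(correlation_matrix(feats2, "kendall")["roundness", "cl"], 1)
  expect_lt(correlation_matrix(feats2, "pearson")["roundness", "cl"], 1)

  # constant column flagged as NA
  feats3 <- features_from_X(orthonormal_X(30, seed = 10))
  feats3$gender <- 0.5
  cm3 <- correlation_matrix(feats3, "pearson")
  expect_true(all(is.na(cm3["gender", ])))
})

test_that("VIF matches the closed form and flags collinearity", {
  X <- orthonormal_X(60)
  expect_equal(unname(vif(features_from_X(X))), rep(1, 9),
               tolerance = 1e-10)

  r <- 0.794
  Xr <- X
  Xr[, 2] <- r * X[, 1] + sqrt(1 - r^2) * X[, 2]
  v <- vif(features_from_X(Xr))
  expect_equal(unname(v[1]), 1 / (1 - r^2), tolerance = 1e-8)
  expect_equal(unname(v[2]), 1 / (1 - r^2), tolerance = 1e-8)
  expect_equal(unname(v[3:9]), rep(1, 7), tolerance = 1e-8)

  Xd <- X
  Xd[, 5] <- X[, 3]
  v2 <- vif(features_from_X(Xd))
  expect_true(is.infinite(v2[["roundness"]]))
  expect_true(is.infinite(v2[["cl"]]))
})

test_that("backward AIC selection respects marginality and drops noise", {
  set.seed(210)
  feats <- small_features(n_clusters = 400, seed = 210)
  # pure-noise response: offset-only law, no covariate effects
  feats$n_followup <- rnbinom(nrow(feats), size = 5, mu = feats$n_baseline)
  sel <- backward_aic_selection(feats)
  # AIC non-increasing along accepted steps
  expect_true(all(diff(sel$trace$aic) <= 0))
  # marginality: every interaction's mains are present
  inter <- sel$terms[grepl(":", sel$terms)]
  mains_needed <- unique(unlist(strsplit(inter, ":")))
  expect_true(all(mains_needed %in% sel$terms))
  # well over half of the 45 noise terms is eliminated (AIC retains a noise
  # term with probability ~0.16, so a handful of survivors is expected)
  expect_lt(length(sel$terms), 45 / 2)
})

test_that("size-growth regression matches exact algebra", {
  growth <- data.frame(n_baseline = c(50L, 200L, 1000L, 40L),
                       n_followup = c(50L, 200L, 1000L, 40L))
  fit <- size_growth_regression(growth)
  expect_equal(fit$slope, 0)
  expect_equal(fit$n_used, 4)

  n <- c(50, 120, 700, 3000, 12000)
  growth2 <- data.frame(n_baseline = n, n_followup = n^1.02)
  # exact fit; lm warns that the summary is unreliable, which is expected
  fit2 <- suppressWarnings(size_growth_regression(growth2))
  expect_equal(fit2$slope, 0.02, tolerance = 1e-10)

  set.seed(66)
  n3 <- sample(40:5000, 400, replace = TRUE)
  y3 <- exp(0.021 * log(n3) + rnorm(400, 0, 0.1)) * n3
  fit3 <- size_growth_regression(data.frame(n_baseline = n3,
                                            n_followup = round(y3)))
  expect_lt(abs(fit3$slope - 0.021), 3 * fit3$se)

  growth4 <- data.frame(n_baseline = c(10, 20), n_followup = c(0, 25))
  expect_equal(size_growth_regression(growth4)$n_excluded, 1)
})

test_that("descriptive table computes SD, CV and adjusted skewness", {
  X <- orthonormal_X(20)
  feats <- features_from_X(X)
  feats$roundness <- c(1, 1, 1, 5, rep(2, 16))
  tab <- summarize_features(feats)
  expect_s3_class(tab, "data.frame")
  r <- tab[tab$variable == "roundness", ]
  v <- feats$roundness
  n <- length(v)
  g1 <- mean((v - mean(v))^3) / mean((v - mean(v))^2)^1.5
  expect_equal(r$skewness, g1 * sqrt(n * (n - 1)) / (n - 2))
  expect_equal(r$cv, sd(v) / mean(v))

  # the worked CV arithmetic: {1,1,1,5} has mean 2, SD 2, CV 1
  sub <- feats[1:4, ]
  sub$roundness <- c(1, 1, 1, 5)
  tab4 <- summarize_features(sub)
  r4 <- tab4[tab4$variable == "roundness", ]
  expect_equal(r4$mean, 2)
  expect_equal(r4$sd, 2)
  expect_equal(r4$cv, 1)

  # constant column: SD = CV = skewness = 0; symmetric column: skewness 0
  constf <- feats
  constf$cl <- 3
  rc <- summarize_features(constf)
  expect_equal(rc[rc$variable == "cl", c("sd", "cv", "skewness")],
               data.frame(sd = 0, cv = 0, skewness = 0),
               ignore_attr = TRUE)
  symf <- feats[1:3, ]
  symf$cl <- c(1, 2, 3)
  rs <- summarize_features(symf)
  expect_equal(rs[rs$variable == "cl", "skewness"], 0)
})
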