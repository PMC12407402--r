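make_fit_inputs <- function(n_births = 400, metric = "benchmark",
                            band_effects = NULL, seed = 19) {
  sw <- small_world()
  dgp <- cohort_dgp(n_births, metric = if (is.null(band_effects)) "benchmark" else metric,
                    band_effects = band_effects,
                    conception_range = sw$conception_range)
  births <- gen_cohort(sw$weather, dgp, seed = seed)$births
  ex <- build_exposures(births, sw$weather, metric)
  list(sw = sw, births = births, ex = ex)
}

test_that("the design matrix has the documented layout", {
  inp <- make_fit_inputs(300, "benchmark")
  dz <- build_design(inp$births, inp$ex, inp$sw$clusters)
  expect_length(dz$heat_cols, 15)
  expect_true(all(c("first_pregnancy", "aboriginal", "age_lt20", "age_ge40") %in%
                    colnames(dz$X)))
  expect_false(any(grepl("25_30", dz$heat_cols))) # omitted band excluded
  expect_length(dz$fe, 2)
  expect_equal(length(dz$y), nrow(dz$X))

  inp2 <- make_fit_inputs(300, "max_and_min")
  dz2 <- build_design(inp2$births, inp2$ex, inp2$sw$clusters)
  expect_length(dz2$heat_cols, 30)
})

test_that("a covariates-only model fits without heat terms", {
  inp <- make_fit_inputs(400)
  empty <- inp$ex["birth_id"]
  attr(empty, "regressors") <- character(0)
  attr(empty, "metric") <- "none"
  fit <- fe_lpm(inp$births, empty, inp$sw$clusters)
  expect_length(fit$heat_terms, 0)
  expect_true(is.na(fit$F_heat$F))
  expect_true(all(c("first_pregnancy", "aboriginal") %in% names(coef(fit))))
})

test_that("single-group absorption equals exact group demeaning", {
  set.seed(5)
  g <- factor(sample(letters[1:6], 80, replace = TRUE))
  y <- rnorm(80)
  X <- matrix(rnorm(160), 80, 2, dimnames = list(NULL, c("x1", "x2")))
  ab <- absorb_fixed_effects(y, X, list(g))
  expect_equal(ab$y, y - ave(y, g), ignore_attr = TRUE)
  expect_equal(ab$X[, 1], X[, 1] - ave(X[, 1], g), ignore_attr = TRUE)
})

test_that("two-group absorption leaves residuals orthogonal to both factors", {
  set.seed(6)
  n <- 300
  g1 <- factor(sample(30, n, replace = TRUE))
  g2 <- factor(sample(12, n, replace = TRUE))
  y <- rnorm(n)
  X <- matrix(rnorm(2 * n), n, 2, dimnames = list(NULL, c("x1", "x2")))
  ab <- absorb_fixed_effects(y, X, list(g1, g2))
  for (v in list(ab$y, ab$X[, 1], ab$X[, 2])) {
    expect_lt(max(abs(tapply(v, g1, sum))), 1e-7)
    expect_lt(max(abs(tapply(v, g2, sum))), 1e-7)
  }
})

test_that("the absorbed path reproduces the explicit dummy-variable path", {
  ow <- oracle_world()
  dgp <- cohort_dgp(450, metric = "benchmark",
                    band_effects = c(max_ge40_t3 = 0.004),
                    conception_range = ow$conception_range)
  births <- gen_cohort(ow$weather, dgp, seed = 27)$births
  ex <- build_exposures(births, ow$weather, "benchmark")
  fit <- fe_lpm(births, ex, ow$clusters)
  dz <- build_design(births, ex, ow$clusters)
  oracle <- dummy_fit_oracle(dz)
  terms <- fit$heat_terms
  expect_equal(fit$coefficients[terms], oracle$heat_coefficients[terms],
               tolerance = 1e-6)
  expect_equal(fit$se[terms], oracle$se[terms], tolerance = 1e-6)
  expect_equal(fit$F_heat$F, oracle$F, tolerance = 1e-6)
  expect_equal(fit$F_heat$df1, oracle$df1)
  expect_equal(fit$F_heat$df2, oracle$df2)
  expect_equal(fit$rss, oracle$rss, tolerance = 1e-8)
  expect_equal(fit$df_absorbed + fit$k, oracle$K)
  expect_equal(fit$r2_within, oracle$r2_within, tolerance = 1e-6)
  expect_equal(fit$adj_r2_within, oracle$adj_r2_within, tolerance = 1e-6)
})

test_that("exact collinearity is dropped without changing estimates", {
  inp <- make_fit_inputs(350, "benchmark", seed = 31)
  fit0 <- fe_lpm(inp$births, inp$ex, inp$sw$clusters)
  ex_dup <- inp$ex
  ex_dup$dup_col <- ex_dup$max_30_35_t1
  attr(ex_dup, "regressors") <- c(attr(inp$ex, "regressors"), "dup_col")
  attr(ex_dup, "metric") <- "benchmark"
  fit1 <- fe_lpm(inp$births, ex_dup, inp$sw$clusters)
  expect_true(("dup_col" %in% fit1$dropped) || ("max_30_35_t1" %in% fit1$dropped))
  shared <- intersect(names(coef(fit0)), names(coef(fit1)))
  expect_equal(coef(fit0)[shared], coef(fit1)[shared], tolerance = 1e-8)
})

test_that("a constant column is absorbed to zero and dropped", {
  inp <- make_fit_inputs(200, "benchmark", seed = 41)
  ex2 <- inp$ex
  ex2$const_col <- 1
  attr(ex2, "regressors") <- c(attr(inp$ex, "regressors"), "const_col")
  attr(ex2, "metric") <- "benchmark"
  fit <- fe_lpm(inp$births, ex2, inp$sw$clusters)
  expect_true("const_col" %in% fit$dropped)
})

test_that("an exact linear outcome is recovered exactly", {
  set.seed(8)
  n <- 200
  g1 <- factor(sample(8, n, replace = TRUE))
  g2 <- factor(sample(5, n, replace = TRUE))
  x <- rnorm(n)
  y <- 2.5 * x + as.numeric(g1) + 0.3 * as.numeric(g2)
  ab <- absorb_fixed_effects(y, cbind(x = x), list(g1, g2))
  ols <- fit_within_ols(ab$y, ab$X)
  expect_equal(unname(ols$coefficients["x"]), 2.5, tolerance = 1e-7)
})

test_that("cluster-robust covariance matches a hand-computed toy example", {
  X <- cbind(x = c(1, 2, 3, 1.5, 2.5, 3.5), z = c(0, 1, 0, 1, 0, 1))
  e <- c(0.5, -0.2, 0.1, -0.4, 0.3, -0.1)
  cl <- factor(c("a", "a", "a", "b", "b", "b"))
  k_abs <- 1L
  V <- cluster_robust_vcov(X, e, cl, k_absorbed = k_abs)
  # explicit score sums per cluster
  sa <- colSums(X[1:3, ] * e[1:3])
  sb <- colSums(X[4:6, ] * e[4:6])
  meat <- tcrossprod(sa) + tcrossprod(sb)
  bread <- solve(crossprod(X))
  N <- 6; G <- 2; K <- k_abs + 2
  V_hand <- (G / (G - 1)) * ((N - 1) / (N - K)) * bread %*% meat %*% bread
  expect_equal(unname(V), unname(V_hand), tolerance = 1e-12)
  expect_error(cluster_robust_vcov(X, e, factor(rep("a", 6))), "at least 2")
})

test_that("one-cluster-per-observation equals the heteroskedastic sandwich", {
  set.seed(9)
  n <- 60
  X <- cbind(x1 = rnorm(n), x2 = rnorm(n))
  e <- rnorm(n)
  V <- cluster_robust_vcov(X, e, factor(seq_len(n)), k_absorbed = 0L)
  bread <- solve(crossprod(X))
  meat <- crossprod(X * e)
  V_hc <- (n / (n - 1)) * ((n - 1) / (n - 2)) * bread %*% meat %*% bread
  expect_equal(unname(V), unname(V_hc), tolerance = 1e-12)
})

test_that("cluster-robust covariance agrees with the sandwich package on a plain regression", {
  skip_if_not_installed("sandwich")
  set.seed(10)
  n <- 120
  d <- data.frame(x1 = rnorm(n), x2 = rnorm(n),
                  cl = factor(sample(10, n, replace = TRUE)))
  d$y <- 1 + 0.5 * d$x1 + rnorm(n)
  lmfit <- lm(y ~ x1 + x2, data = d)
  X <- model.matrix(lmfit)
  V_pkg <- sandwich::vcovCL(lmfit, cluster = d$cl, type = "HC1")
  V_own <- cluster_robust_vcov(X, residuals(lmfit), d$cl, k_absorbed = 0L)
  expect_equal(unname(V_own), unname(V_pkg), tolerance = 1e-10)
})

test_that("a single-term Wald F equals the squared cluster-robust t", {
  inp <- make_fit_inputs(300, "trimester_average", seed = 43)
  fit <- fe_lpm(inp$births, inp$ex, inp$sw$clusters)
  w <- joint_wald_F(fit, terms = "avg_tmax_t2")
  tstat <- fit$coefficients["avg_tmax_t2"] / fit$se["avg_tmax_t2"]
  expect_equal(w$F, unname(tstat^2), tolerance = 1e-10)
  expect_equal(w$df1, 1L)
  # all-zero coefficients give F = 0, p = 1
  fit0 <- fit
  fit0$coefficients[] <- 0
  w0 <- joint_wald_F(fit0)
  expect_equal(w0$F, 0)
  expect_equal(w0$p_value, 1)
})

test_that("fit statistics behave as definitions require", {
  sw <- small_world()
  dgp <- cohort_dgp(500, conception_range = sw$conception_range)
  births <- gen_cohort(sw$weather, dgp, seed = 51)$births
  set.seed(52)
  births$noise_outcome <- rnorm(nrow(births))
  ex <- build_exposures(births, sw$weather, "trimester_average")
  fit <- fe_lpm(births, ex, sw$clusters, outcome = "noise_outcome")
  expect_lt(abs(fit$adj_r2_within), 0.05) # pure noise: near zero, may be < 0

  # equal regressor count: AIC ranking equals RSS ranking
  ex2 <- build_exposures(births, sw$weather, "heatwave_count")
  fit2 <- fe_lpm(births, ex2, sw$clusters, outcome = "noise_outcome")
  expect_equal(fit$aic < fit2$aic, fit$rss < fit2$rss)
  expect_equal(fit$n_obs, nrow(births))
  # covariance is symmetric positive semi-definite
  expect_equal(fit$vcov, t(fit$vcov), tolerance = 1e-12)
  expect_true(all(eigen(fit$vcov, symmetric = TRUE, only.values = TRUE)$values > -1e-10))
})
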