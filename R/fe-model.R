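age_band_levels <- function() c("lt20", "20_24", "25_29", "30_34", "35_39", "ge40")

#' Assemble the regression design for the fixed-effects model
#'
#' Builds the outcome vector, the heat + covariate regressor matrix, the two
#' absorbed fixed-effect factors and the cluster labels for one model. The
#' covariates are a first-pregnancy indicator, an Aboriginal indicator and
#' one-hot 5-year mother-age bands (reference band 25-29). The fixed effects
#' are location x conception-month x sex and conception month-year. Omitted
#' heat bands never enter the design. Rows with any missing value are dropped
#' and counted.
#'
#' @param births birth records with `birth_id`, `location_id`, `birth_date`,
#'   `gestational_weeks`, `sex`, `aboriginal`, `first_pregnancy`,
#'   `mother_age_band` and the outcome column.
#' @param exposures a [build_exposures()] (or [combine_exposures()]) table.
#' @param clusters a `location_id`/`cluster_id` data frame from
#'   [cluster_max_diameter()], or `NULL` to cluster at the location level.
#' @param outcome outcome column name (default `"preterm"`).
#' @return a list with `y`, `X` (regressors), `heat_cols`, `fe` (list of two
#'   factors), `cluster` (factor), `birth_id`, `n_dropped_na`.
#' @export
build_design <- function(births, exposures, clusters = NULL, outcome = "preterm") {
  assert_columns(births, c("birth_id", "location_id", "birth_date",
                           "gestational_weeks", "sex", "aboriginal",
                           "first_pregnancy", "mother_age_band", outcome),
                 "births")
  heat_cols <- attr(exposures, "regressors") %||%
    setdiff(names(exposures), "birth_id")
  ex <- exposures[match(births$birth_id, exposures$birth_id), , drop = FALSE]
  if (anyNA(ex$birth_id)) stop("exposures do not cover every birth id")

  y <- as.numeric(births[[outcome]])
  if (length(unique(y[!is.na(y)])) < 2L) stop("outcome has zero variance")

  conc <- conception_date(births$birth_date, births$gestational_weeks)
  cm <- month_of(conc)
  cy <- year_of(conc)
  fe_loc <- factor(paste(births$location_id, cm, births$sex, sep = ":"))
  fe_my <- factor(paste(cy, sprintf("%02d", cm), sep = "-"))

  ab <- factor(as.character(births$mother_age_band), levels = age_band_levels())
  if (any(is.na(ab) & !is.na(births$mother_age_band))) {
    stop("unknown mother_age_band level(s); expected ",
         paste(age_band_levels(), collapse = ", "))
  }
  age_ref <- "25_29"
  age_dummy_levels <- setdiff(age_band_levels(), age_ref)
  A <- sapply(age_dummy_levels, function(l) as.numeric(ab == l))
  colnames(A) <- paste0("age_", age_dummy_levels)

  Xh <- as.matrix(ex[, heat_cols, drop = FALSE])
  X <- cbind(Xh,
             first_pregnancy = as.numeric(births$first_pregnancy),
             aboriginal = as.numeric(births$aboriginal),
             A)

  if (is.null(clusters)) {
    cl <- factor(births$location_id)
  } else {
    assert_columns(clusters, c("location_id", "cluster_id"), "clusters")
    cid <- clusters$cluster_id[match(births$location_id, clusters$location_id)]
    if (anyNA(cid)) stop("some locations have no cluster assignment")
    cl <- factor(cid)
  }

  keep <- !is.na(y) & complete.cases(X)
  n_dropped <- sum(!keep)
  list(
    y = y[keep],
    X = X[keep, , drop = FALSE],
    heat_cols = heat_cols,
    fe = list(loc_month_sex = droplevels(fe_loc[keep]),
              month_year = droplevels(fe_my[keep])),
    cluster = droplevels(cl[keep]),
    birth_id = births$birth_id[keep],
    n_dropped_na = n_dropped
  )
}

#' Absorb fixed effects by alternating within-group demeaning
#'
#' Removes one or two fixed-effect group structures from `y` and the columns
#' of `X` by iterated within-group demeaning (alternating projections),
#' sweeping until the largest absolute adjustment in a full sweep falls below
#' `tol` or `max_sweeps` is reached. With a single group one pass is exact.
#'
#' @param y numeric outcome vector.
#' @param X numeric regressor matrix.
#' @param fe_groups a list of one or two factors of length `length(y)`.
#' @param tol convergence tolerance on the per-sweep adjustment
#'   (default 1e-10).
#' @param max_sweeps sweep cap (default 10000).
#' @return list with demeaned `y`, `X`, the sweep count `sweeps`, and the
#'   achieved `delta`.
#' @export
absorb_fixed_effects <- function(y, X, fe_groups, tol = 1e-10, max_sweeps = 10000L) {
  stopifnot(length(fe_groups) >= 1L, length(fe_groups) <= 2L)
  fe_groups <- lapply(fe_groups, function(g) droplevels(as.factor(g)))
  M <- cbind(y, X)
  g1 <- as.integer(fe_groups[[1L]]) - 1L
  L1 <- nlevels(fe_groups[[1L]])
  if (length(fe_groups) == 2L) {
    g2 <- as.integer(fe_groups[[2L]]) - 1L
    L2 <- nlevels(fe_groups[[2L]])
  } else {
    g2 <- integer(length(y))
    L2 <- 0L
  }
  res <- demean_cpp(M, g1, g2, L1, L2, tol, as.integer(max_sweeps))
  if (res$delta >= tol && length(fe_groups) == 2L) {
    stop("fixed-effect absorption did not converge: achieved ",
         format(res$delta), " after ", res$sweeps, " sweeps (tol ", tol, ")")
  }
  Md <- res$M
  colnames(Md) <- c("y", colnames(X))
  list(y = Md[, 1L], X = Md[, -1L, drop = FALSE],
       sweeps = res$sweeps, delta = res$delta)
}

# degrees of freedom absorbed by the FE structure: for two crossed factors,
# L1 + L2 - (number of connected components of their bipartite graph)
fe_absorbed_dof <- function(fe_groups) {
  fe_groups <- lapply(fe_groups, function(g) droplevels(as.factor(g)))
  if (length(fe_groups) == 1L) return(nlevels(fe_groups[[1L]]))
  f1 <- as.integer(fe_groups[[1L]]); L1 <- nlevels(fe_groups[[1L]])
  f2 <- as.integer(fe_groups[[2L]]) + L1; L2 <- nlevels(fe_groups[[2L]])
  parent <- seq_len(L1 + L2)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  pairs <- unique(cbind(f1, f2))
  for (r in seq_len(nrow(pairs))) {
    a <- find(pairs[r, 1L]); b <- find(pairs[r, 2L])
    if (a != b) parent[b] <- a
  }
  ncomp <- length(unique(vapply(seq_len(L1 + L2), find, integer(1))))
  L1 + L2 - ncomp
}

#' Within OLS on demeaned data
#'
#' Least squares on the demeaned design; collinear columns (including
#' columns demeaned to zero by the fixed effects) are dropped by pivoted QR
#' and logged.
#'
#' @param y demeaned outcome.
#' @param X demeaned regressor matrix.
#' @param qr_tol rank tolerance passed to [qr()].
#' @return list with `coefficients` (named, kept columns only), `kept`,
#'   `dropped`, `residuals`, `rss`, `qr`.
#' @export
fit_within_ols <- function(y, X, qr_tol = 1e-7) {
  qrx <- qr(X, tol = qr_tol)
  r <- qrx$rank
  if (r == 0L) stop("design has rank zero after absorbing fixed effects")
  kept <- colnames(X)[qrx$pivot[seq_len(r)]]
  dropped <- colnames(X)[qrx$pivot[-seq_len(r)]]
  b_all <- qr.coef(qrx, y)
  b <- b_all[kept]
  e <- y - X[, kept, drop = FALSE] %*% b
  list(coefficients = b, kept = kept, dropped = dropped,
       residuals = as.numeric(e), rss = sum(e^2), qr = qrx)
}

#' Cluster-robust covariance (Stata areg convention)
#'
#' Sandwich covariance with scores summed within clusters and the
#' finite-sample factor `G/(G-1) * (N-1)/(N-K)`, where `K` counts the
#' absorbed fixed effects plus the kept regressors.
#'
#' @param X demeaned regressor matrix (kept columns only).
#' @param residuals within-OLS residuals.
#' @param cluster factor of cluster memberships (needs at least 2 clusters).
#' @param k_absorbed degrees of freedom absorbed by the fixed effects.
#' @return the covariance matrix of the kept coefficients.
#' @export
cluster_robust_vcov <- function(X, residuals, cluster, k_absorbed = 0L) {
  cluster <- droplevels(as.factor(cluster))
  G <- nlevels(cluster)
  if (G < 2L) stop("cluster-robust covariance needs at least 2 clusters")
  N <- nrow(X)
  K <- k_absorbed + ncol(X)
  if (N - K <= 0) stop("no residual degrees of freedom (N <= K)")
  bread <- chol2inv(chol(crossprod(X)))
  S <- rowsum(X * residuals, cluster)
  meat <- crossprod(S)
  adj <- (G / (G - 1)) * ((N - 1) / (N - K))
  V <- adj * bread %*% meat %*% bread
  dimnames(V) <- list(colnames(X), colnames(X))
  V
}

classical_vcov <- function(X, residuals, k_absorbed = 0L) {
  N <- nrow(X)
  K <- k_absorbed + ncol(X)
  sigma2 <- sum(residuals^2) / (N - K)
  V <- sigma2 * chol2inv(chol(crossprod(X)))
  dimnames(V) <- list(colnames(X), colnames(X))
  V
}

pseudo_inverse <- function(V, tol = 1e-12) {
  s <- svd(V)
  pos <- s$d > tol * max(s$d)
  s$v[, pos, drop = FALSE] %*% (t(s$u[, pos, drop = FALSE]) / s$d[pos])
}

#' Joint Wald F-test of a coefficient group
#'
#' Wald statistic `b' V^-1 b` on the fitted covariance, divided by the number
#' of tested terms; compared against `F(df1, G - 1)` under clustering
#' (`df2 = N - K` for classical covariance).
#'
#' @param fit an [fe_lpm()] fit.
#' @param terms coefficient names to test jointly (default: the fit's heat
#'   term group).
#' @return list `F`, `df1`, `df2`, `p_value`.
#' @export
joint_wald_F <- function(fit, terms = NULL) {
  terms <- terms %||% fit$heat_terms
  terms <- intersect(terms, names(fit$coefficients))
  if (!length(terms)) stop("no tested terms present in the fit")
  b <- fit$coefficients[terms]
  V <- fit$vcov[terms, terms, drop = FALSE]
  Vi <- tryCatch(solve(V), error = function(e) {
    warning("singular covariance sub-block; using a pseudo-inverse")
    pseudo_inverse(V)
  })
  W <- drop(t(b) %*% Vi %*% b)
  df1 <- length(terms)
  df2 <- if (fit$vcov_type == "cluster") fit$n_clusters - 1L else fit$df_resid
  Fst <- W / df1
  list(F = Fst, df1 = df1, df2 = df2,
       p_value = pf(Fst, df1, df2, lower.tail = FALSE))
}

#' Fit the absorbed fixed-effects linear probability model
#'
#' Estimates a linear probability model of a binary (or continuous) outcome
#' on heat-metric regressors and individual covariates, absorbing
#' location x conception-month x sex and conception month-year fixed effects
#' by alternating demeaning, with cluster-robust (Stata-areg convention)
#' standard errors, a joint Wald F-test of the heat term group, the within
#' adjusted R-squared and a Gaussian AIC.
#'
#' The AIC parameter count covers the non-absorbed regressors plus the
#' intercept and error variance; the absorbed fixed-effect count is excluded
#' but identical across the metric models being compared (set
#' `aic_include_fe = TRUE` to include it). Predicted values of the linear
#' probability model may leave \[0, 1\]; they are not clipped here.
#'
#' @param births birth records (see [build_design()]).
#' @param exposures exposure table for one metric (or combined metrics).
#' @param clusters location-to-cluster assignment, or `NULL` to cluster at
#'   the location level.
#' @param outcome outcome column (default `"preterm"`).
#' @param vcov `"cluster"` (default) or `"classical"`.
#' @param aic_include_fe include the absorbed-FE count in the AIC penalty.
#' @param tol,max_sweeps absorption controls, see [absorb_fixed_effects()].
#' @return an object of class `fe_fit`: coefficients, `se`, `vcov`,
#'   `heat_terms` (kept), `dropped`, `n_obs`, `n_clusters`, `rss`,
#'   `df_absorbed`, `df_resid`, `r2_within`, `adj_r2_within`, `aic`,
#'   `F_heat`, `ybar`, `metric`, `sweeps`.
#' @export
fe_lpm <- function(births, exposures, clusters = NULL, outcome = "preterm",
                   vcov = c("cluster", "classical"), aic_include_fe = FALSE,
                   tol = 1e-10, max_sweeps = 10000L) {
  vcov <- match.arg(vcov)
  dz <- build_design(births, exposures, clusters, outcome)
  ab <- absorb_fixed_effects(dz$y, dz$X, dz$fe, tol = tol, max_sweeps = max_sweeps)
  ols <- fit_within_ols(ab$y, ab$X)
  Xk <- ab$X[, ols$kept, drop = FALSE]
  df_absorbed <- fe_absorbed_dof(dz$fe)
  N <- length(dz$y)
  k <- length(ols$kept)
  K <- df_absorbed + k
  df_resid <- N - K
  if (df_resid <= 0) stop("no residual degrees of freedom")
  G <- nlevels(droplevels(dz$cluster))
  V <- if (vcov == "cluster") {
    cluster_robust_vcov(Xk, ols$residuals, dz$cluster, df_absorbed)
  } else {
    classical_vcov(Xk, ols$residuals, df_absorbed)
  }
  tss_within <- sum(ab$y^2)
  r2_within <- 1 - ols$rss / tss_within
  adj_r2_within <- 1 - (1 - r2_within) * (N - df_absorbed) / (N - df_absorbed - k)
  p_aic <- k + 2L + if (aic_include_fe) df_absorbed else 0L
  sigma2 <- ols$rss / N
  if (sigma2 <= 0) stop("zero residual variance; AIC undefined")
  aic <- N * (log(2 * pi * sigma2) + 1) + 2 * p_aic

  fit <- structure(list(
    coefficients = ols$coefficients,
    se = sqrt(diag(V)),
    vcov = V,
    vcov_type = vcov,
    heat_terms = intersect(dz$heat_cols, ols$kept),
    heat_terms_all = dz$heat_cols,
    dropped = ols$dropped,
    residuals = ols$residuals,
    n_obs = N,
    n_clusters = G,
    cluster = dz$cluster,
    rss = ols$rss,
    df_absorbed = df_absorbed,
    k = k,
    df_resid = df_resid,
    r2_within = r2_within,
    adj_r2_within = adj_r2_within,
    aic = aic,
    ybar = mean(dz$y),
    metric = attr(exposures, "metric") %||% "custom",
    outcome = outcome,
    n_dropped_na = dz$n_dropped_na,
    sweeps = ab$sweeps
  ), class = "fe_fit")
  fit$F_heat <- if (length(fit$heat_terms)) joint_wald_F(fit) else
    list(F = NA_real_, df1 = 0L, df2 = NA_integer_, p_value = NA_real_)
  fit
}

#' @export
coef.fe_fit <- function(object, ...) object$coefficients

#' @export
vcov.fe_fit <- function(object, ...) object$vcov

#' Coefficient table of a fitted model
#'
#' @param fit an [fe_lpm()] fit.
#' @return a data frame with `term`, `estimate`, `se`, `t`, `p_value` and a
#'   flag for heat-metric terms.
#' @export
coef_table <- function(fit) {
  stopifnot(inherits(fit, "fe_fit"))
  tv <- fit$coefficients / fit$se
  df2 <- if (fit$vcov_type == "cluster") fit$n_clusters - 1L else fit$df_resid
  data.frame(
    term = names(fit$coefficients),
    estimate = unname(fit$coefficients),
    se = unname(fit$se),
    t = unname(tv),
    p_value = unname(2 * pf(tv^2, 1, df2, lower.tail = FALSE)),
    heat_term = names(fit$coefficients) %in% fit$heat_terms,
    stringsAsFactors = FALSE
  )
}

#' @export
print.fe_fit <- function(x, ...) {
  cat("Absorbed fixed-effects linear probability model\n")
  cat("  metric:", x$metric, "  outcome:", x$outcome, "\n")
  cat(sprintf("  n = %d, clusters = %d, absorbed dof = %d, kept regressors = %d\n",
              x$n_obs, x$n_clusters, x$df_absorbed, x$k))
  cat(sprintf("  heat F = %.3f (df1 = %d, df2 = %d, p = %.4g)\n",
              x$F_heat$F, x$F_heat$df1, x$F_heat$df2, x$F_heat$p_value))
  cat(sprintf("  within adj R2 = %.4f, AIC = %.1f\n", x$adj_r2_within, x$aic))
  if (length(x$dropped)) {
    cat("  dropped collinear:", paste(x$dropped, collapse = ", "), "\n")
  }
  invisible(x)
}
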