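# Independent oracles and shared fixtures for the test suite.

# Second, independent transcription of Stull's wet-bulb fit, written
# term-by-term with explicit intermediate quantities.
stull_oracle <- function(t, rh) {
  term1 <- t * atan(0.151977 * (rh + 8.313659)^0.5)
  term2 <- atan(t + rh)
  term3 <- -atan(rh - 1.676331)
  term4 <- 0.00391838 * (rh^(3 / 2)) * atan(0.023101 * rh)
  term5 <- -4.686035
  term1 + term2 + term3 + term4 + term5
}

# Spherical law of cosines distance, miles.
slc_miles <- function(lat1, lon1, lat2, lon2, r = 3958.8) {
  p1 <- lat1 * pi / 180; p2 <- lat2 * pi / 180
  dl <- (lon2 - lon1) * pi / 180
  cosang <- sin(p1) * sin(p2) + cos(p1) * cos(p2) * cos(dl)
  r * acos(pmin(pmax(cosang, -1), 1))
}

# Brute-force heatwave scan: for every start/end window test the run rule.
brute_force_heatwaves <- function(ehf) {
  pos <- !is.na(ehf) & ehf > 0
  n <- length(pos)
  events <- list()
  i <- 1L
  while (i <= n) {
    if (pos[i]) {
      j <- i
      while (j < n && pos[j + 1L]) j <- j + 1L
      if (j - i + 1L >= 3L) events[[length(events) + 1L]] <- c(start = i, end = j)
      i <- j + 1L
    } else {
      i <- i + 1L
    }
  }
  events
}

# Full dummy-variable regression path with a hand-computed cluster sandwich,
# the oracle for the absorbed-FE implementation.
dummy_fit_oracle <- function(design) {
  y <- design$y
  X <- design$X
  f1 <- design$fe[[1]]
  f2 <- design$fe[[2]]
  cluster <- design$cluster
  D <- cbind(stats::model.matrix(~f1), stats::model.matrix(~ 0 + f2))
  W <- cbind(X, D)
  fit <- stats::lm.fit(W, y)
  kept <- !is.na(fit$coefficients)
  K <- fit$rank
  Wk <- W[, kept, drop = FALSE]
  e <- fit$residuals
  N <- length(y)
  G <- nlevels(droplevels(cluster))
  bread <- solve(crossprod(Wk))
  scores <- Wk * e
  S <- rowsum(scores, cluster)
  meat <- crossprod(S)
  V <- (G / (G - 1)) * ((N - 1) / (N - K)) * bread %*% meat %*% bread
  dimnames(V) <- list(colnames(Wk), colnames(Wk))
  heat_kept <- intersect(design$heat_cols, colnames(Wk))
  b_h <- fit$coefficients[heat_kept]
  V_h <- V[heat_kept, heat_kept, drop = FALSE]
  Wald <- drop(t(b_h) %*% solve(V_h) %*% b_h)
  q <- length(heat_kept)
  # within R-squared from FE-only projection residuals
  fe_fit <- stats::lm.fit(D, y)
  y_dem <- fe_fit$residuals
  rss <- sum(e^2)
  df_absorbed <- fe_fit$rank
  k <- K - df_absorbed
  r2w <- 1 - rss / sum(y_dem^2)
  adj_r2w <- 1 - (1 - r2w) * (N - df_absorbed) / (N - df_absorbed - k)
  list(coefficients = fit$coefficients[colnames(X)][!is.na(fit$coefficients[colnames(X)])],
       heat_coefficients = b_h,
       se = sqrt(diag(V_h)),
       F = Wald / q, df1 = q, df2 = G - 1,
       rss = rss, K = K, df_absorbed = df_absorbed,
       r2_within = r2w, adj_r2_within = adj_r2w)
}

# --- shared simulated world (computed once per test run) ------------------

.sim_cache <- new.env(parent = emptyenv())

# Small two-zone world for unit tests: 4 + 4 locations, 4.5 years.
small_world <- function() {
  if (!is.null(.sim_cache$small)) return(.sim_cache$small)
  locs <- nt_locations(4, 4, seed = 7)
  dates <- as.Date(c("2000-06-01", "2004-12-31"))
  wx <- rbind(
    gen_weather(climate_zone_params("tropical"),
                locs$location_id[locs$zone == "tropical"], dates, seed = 11),
    gen_weather(climate_zone_params("arid"),
                locs$location_id[locs$zone == "arid"], dates, seed = 12)
  )
  wx <- excess_heat_factor(derive_daily_fields(wx))
  .sim_cache$small <- list(
    locations = locs, weather = wx,
    clusters = cluster_max_diameter(locs),
    conception_range = as.Date(c("2001-03-01", "2003-12-31"))
  )
  .sim_cache$small
}

# World for oracle-equivalence checks: enough geoclusters (~20) that a
# 15-term cluster-robust Wald block is well-conditioned at a few hundred rows.
oracle_world <- function() {
  if (!is.null(.sim_cache$oracle)) return(.sim_cache$oracle)
  locs <- nt_locations(12, 12, seed = 3)
  dates <- as.Date(c("2000-06-01", "2003-12-31"))
  wx <- rbind(
    gen_weather(climate_zone_params("tropical"),
                locs$location_id[locs$zone == "tropical"], dates, seed = 11),
    gen_weather(climate_zone_params("arid"),
                locs$location_id[locs$zone == "arid"], dates, seed = 12)
  )
  .sim_cache$oracle <- list(
    locations = locs, weather = wx,
    clusters = cluster_max_diameter(locs),
    conception_range = as.Date(c("2001-01-01", "2002-12-31"))
  )
  .sim_cache$oracle
}

# Study-scale world for the simulation-based acceptance properties:
# 28 + 28 locations (41 geoclusters), 9.5 years of weather.
study_world <- function() {
  if (!is.null(.sim_cache$study)) return(.sim_cache$study)
  locs <- nt_locations(28, 28, seed = 7)
  dates <- as.Date(c("2000-06-01", "2009-12-31"))
  wx <- rbind(
    gen_weather(climate_zone_params("tropical"),
                locs$location_id[locs$zone == "tropical"], dates, seed = 11),
    gen_weather(climate_zone_params("arid"),
                locs$location_id[locs$zone == "arid"], dates, seed = 12)
  )
  wx <- excess_heat_factor(derive_daily_fields(wx))
  .sim_cache$study <- list(
    locations = locs, weather = wx,
    clusters = cluster_max_diameter(locs),
    conception_range = as.Date(c("2001-03-01", "2008-09-30"))
  )
  .sim_cache$study
}

# The planted max-and-min truth used across simulation tests: risk loads
# mostly on minimum-temperature bands (prolonged-heat channel) with smaller
# maximum-band effects, per-day probability effects.
planted_truth <- function() {
  c(min_ge25_t2 = 0.005, min_ge25_t1 = 0.005, min_lt5_t1 = -0.004,
    min_5_10_t3 = -0.003, max_35_40_t3 = 0.002, max_ge40_t3 = 0.003,
    max_lt20_t2 = -0.002)
}

# Deterministic constant-value weather builder for hand-tally tests.
toy_weather <- function(location_id, start, values) {
  n <- length(values$tmax)
  data.frame(
    location_id = location_id,
    date = as.Date(start) + seq_len(n) - 1L,
    tmax_c = values$tmax,
    tmin_c = values$tmin %||% (values$tmax - 8),
    rh_pct = values$rh %||% rep(50, n),
    stringsAsFactors = FALSE
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
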