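#' Day-of-year climatology of a weather series
#'
#' Averages each base daily field (`tmax_c`, `tmin_c`, `rh_pct`) by calendar
#' day of year over complete reference years, per location, then recomputes
#' the derived fields (daily mean and wet-bulb temperatures) from the
#' averaged base fields rather than averaging them post hoc. February 29 is
#' filled from February 28 when absent. Incomplete calendar years are
#' excluded with a warning.
#'
#' @param weather a daily weather data frame.
#' @param reference_years optional integer vector restricting the years used.
#' @return a `climatology` data frame: `location_id`, `doy` (1-366, leap-year
#'   numbering), `month_day`, `tmax_c`, `tmin_c`, `rh_pct`, `tmean_c`,
#'   `wb_mean_c`, `wb_max_c`.
#' @export
day_of_year_climatology <- function(weather, reference_years = NULL) {
  assert_columns(weather, c("location_id", "date", "tmax_c", "tmin_c", "rh_pct"),
                 "weather")
  weather$date <- as_date(weather$date)
  yr <- year_of(weather$date)
  if (!is.null(reference_years)) {
    weather <- weather[yr %in% reference_years, , drop = FALSE]
    yr <- yr[yr %in% reference_years]
  }
  days_in_year <- function(y) 365L + as.integer((y %% 4 == 0 & y %% 100 != 0) | y %% 400 == 0)
  out <- list()
  for (loc in unique(weather$location_id)) {
    wl <- weather[weather$location_id == loc, , drop = FALSE]
    ylc <- year_of(wl$date)
    cov_by_year <- table(ylc)
    complete <- as.integer(names(cov_by_year))[
      as.integer(cov_by_year) == days_in_year(as.integer(names(cov_by_year)))]
    if (!length(complete)) stop("no complete reference year for location ", loc)
    if (length(complete) < length(cov_by_year)) {
      warning("excluding ", length(cov_by_year) - length(complete),
              " incomplete year(s) for location ", loc)
    }
    wl <- wl[ylc %in% complete, , drop = FALSE]
    md <- format(wl$date, "%m-%d")
    agg <- aggregate(wl[, c("tmax_c", "tmin_c", "rh_pct")], list(month_day = md), mean)
    if (!"02-29" %in% agg$month_day) {
      feb28 <- agg[agg$month_day == "02-28", , drop = FALSE]
      feb28$month_day <- "02-29"
      agg <- rbind(agg, feb28)
    }
    agg <- agg[order(agg$month_day), , drop = FALSE]
    # leap-year day-of-year numbering for the canonical 366-entry profile
    agg$doy <- day_of_year(as.Date(paste0("2000-", agg$month_day)))
    agg <- agg[order(agg$doy), , drop = FALSE]
    agg$location_id <- loc
    out[[loc]] <- agg
  }
  res <- do.call(rbind, out)
  res <- derive_daily_fields_cols(res)
  res <- res[, c("location_id", "doy", "month_day", "tmax_c", "tmin_c",
                 "rh_pct", "tmean_c", "wb_mean_c", "wb_max_c")]
  rownames(res) <- NULL
  class(res) <- c("climatology", "data.frame")
  res
}

# derived fields without the location/date checks of derive_daily_fields()
derive_daily_fields_cols <- function(df) {
  df$tmean_c <- (df$tmax_c + df$tmin_c) / 2
  df$wb_mean_c <- wet_bulb_stull(df$tmean_c, df$rh_pct, warn = FALSE)
  df$wb_max_c <- wet_bulb_stull(df$tmax_c, df$rh_pct, warn = FALSE)
  df
}

#' Materialise a climatology as a dated daily weather series
#'
#' @param profile a [day_of_year_climatology()] result.
#' @param start,end inclusive date range.
#' @return a daily weather data frame whose values repeat the climatological
#'   annual cycle.
#' @export
climatology_series <- function(profile, start, end) {
  start <- as_date(start); end <- as_date(end)
  stopifnot(start <= end)
  dates <- seq(start, end, by = "day")
  md <- format(dates, "%m-%d")
  out <- list()
  for (loc in unique(profile$location_id)) {
    pl <- profile[profile$location_id == loc, , drop = FALSE]
    idx <- match(md, pl$month_day)
    if (anyNA(idx)) stop("climatology profile for ", loc, " is incomplete")
    block <- pl[idx, c("tmax_c", "tmin_c", "rh_pct", "tmean_c",
                       "wb_mean_c", "wb_max_c"), drop = FALSE]
    out[[loc]] <- data.frame(location_id = loc, date = dates, block,
                             stringsAsFactors = FALSE, row.names = NULL)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

scenario_birth_month <- function(scenario) {
  # gestation over the hottest 9 months ends in May; over the coolest 9
  # months it ends in November
  switch(scenario, hottest9 = 5L, coolest9 = 11L,
         stop("scenario must be 'hottest9' or 'coolest9'"))
}

#' Exposure vectors under a counterfactual seasonal scenario
#'
#' Builds the exposure a pregnancy would have accumulated under typical
#' (climatological) weather at its own location, with the conception date set
#' so that a 39-week gestation ends mid-month of the scenario's birth month:
#' May for the `hottest9` scenario, November for `coolest9`. Exposure is then
#' computed from the climatology exactly as for real weather.
#'
#' @param profile a [day_of_year_climatology()] result covering every birth's
#'   location.
#' @param scenario `"hottest9"` or `"coolest9"`.
#' @param metric a [heat_metric()] object or name.
#' @param births the cohort (used for `birth_id` to `location_id` mapping).
#' @param reference_year calendar year anchoring the scenario birth date
#'   (default 2005; the climatology repeats annually, so only the month
#'   placement matters).
#' @return an exposure table aligned with `births$birth_id`.
#' @export
scenario_exposure <- function(profile, scenario, metric, births,
                              reference_year = 2005L) {
  metric <- as_heat_metric(metric)
  assert_columns(births, c("birth_id", "location_id"), "births")
  birth_date <- as.Date(sprintf("%d-%02d-15", reference_year,
                                scenario_birth_month(scenario)))
  conc <- birth_date - 273L
  locs <- unique(births$location_id)
  missing_loc <- setdiff(locs, unique(profile$location_id))
  if (length(missing_loc)) {
    stop("no climatology profile for location(s): ",
         paste(missing_loc, collapse = ", "))
  }
  series <- climatology_series(profile[profile$location_id %in% locs, , drop = FALSE],
                               conc - 40L, birth_date + 1L)
  pseudo <- data.frame(birth_id = locs, location_id = locs,
                       conception_date = conc, birth_date = birth_date,
                       gestational_weeks = 39L, stringsAsFactors = FALSE)
  ex_loc <- build_exposures(pseudo, series, metric)
  ex <- ex_loc[match(births$location_id, ex_loc$birth_id), , drop = FALSE]
  ex$birth_id <- births$birth_id
  rownames(ex) <- NULL
  attr(ex, "metric") <- metric$name
  attr(ex, "omitted") <- metric_omitted(metric)
  attr(ex, "regressors") <- attr(ex_loc, "regressors")
  attr(ex, "scenario") <- scenario
  ex
}

#' Counterfactual predicted preterm rates under seasonal scenarios
#'
#' Predicts the cohort outcome rate if every pregnancy had experienced
#' typical hottest-9-months or coolest-9-months exposure: the observed cohort
#' rate plus the mean heat-term contrast
#' `mean((X_scenario - X_factual) %*% b_heat)`. Fixed effects and covariates
#' are held at their factual values, so they cancel exactly in the scenario
#' difference. Confidence intervals (68/80/95% by default) for the
#' heat-coefficient-driven component come from the delta method on the
#' cluster-robust heat-coefficient covariance; `method = "simulation"` draws
#' from the coefficient distribution instead.
#'
#' @param fit an [fe_lpm()] fit.
#' @param factual_exposures the exposure table used in the fit.
#' @param scenario_exposures a named list with elements `hottest9` and
#'   `coolest9` from [scenario_exposure()].
#' @param levels confidence levels (default `c(0.68, 0.80, 0.95)`).
#' @param method `"delta"` (default) or `"simulation"`.
#' @param n_draws draws for `method = "simulation"`.
#' @param clip clip reported predicted rates to \[0, 1\] (flagged; default
#'   `TRUE`). The difference is never clipped.
#' @return an object of class `heat_prediction`: a data frame with rows
#'   `hottest9`, `coolest9`, `difference` and columns `estimate`, `se`,
#'   `lo_68`/`hi_68`, `lo_80`/`hi_80`, `lo_95`/`hi_95`, `clipped`.
#' @export
predict_rates <- function(fit, factual_exposures, scenario_exposures,
                          levels = c(0.68, 0.80, 0.95),
                          method = c("delta", "simulation"),
                          n_draws = 10000L, clip = TRUE) {
  method <- match.arg(method)
  stopifnot(inherits(fit, "fe_fit"))
  if (!all(c("hottest9", "coolest9") %in% names(scenario_exposures))) {
    stop("scenario_exposures must contain 'hottest9' and 'coolest9'")
  }
  terms <- fit$heat_terms
  if (!length(terms)) stop("fit has no heat terms to contrast")
  for (nm in c("hottest9", "coolest9")) {
    missing_t <- setdiff(terms, names(scenario_exposures[[nm]]))
    if (length(missing_t)) {
      stop("scenario '", nm, "' lacks regressor(s): ",
           paste(missing_t, collapse = ", "))
    }
  }
  Xf <- as.matrix(factual_exposures[, terms, drop = FALSE])
  b <- fit$coefficients[terms]
  V <- fit$vcov[terms, terms, drop = FALSE]

  contrast <- function(scen) {
    Xs <- scenario_exposures[[scen]]
    Xs <- as.matrix(Xs[match(factual_exposures$birth_id, Xs$birth_id),
                       terms, drop = FALSE])
    colMeans(Xs - Xf)
  }
  a_hot <- contrast("hottest9")
  a_cool <- contrast("coolest9")
  a_diff <- a_hot - a_cool

  est <- c(hottest9 = fit$ybar + sum(a_hot * b),
           coolest9 = fit$ybar + sum(a_cool * b),
           difference = sum(a_diff * b))
  ses <- c(hottest9 = sqrt(drop(t(a_hot) %*% V %*% a_hot)),
           coolest9 = sqrt(drop(t(a_cool) %*% V %*% a_cool)),
           difference = sqrt(drop(t(a_diff) %*% V %*% a_diff)))

  out <- data.frame(scenario = names(est), estimate = unname(est),
                    se = unname(ses), stringsAsFactors = FALSE)
  if (method == "simulation") {
    R <- chol(V + diag(1e-14, nrow(V)))
    draws <- matrix(rnorm(n_draws * length(b)), n_draws) %*% R
    draws <- sweep(draws, 2L, b, `+`)
    sims <- cbind(fit$ybar + draws %*% a_hot,
                  fit$ybar + draws %*% a_cool,
                  draws %*% a_diff)
    colnames(sims) <- c("hottest9", "coolest9", "difference")
  }
  for (lv in levels) {
    z <- qnorm(1 - (1 - lv) / 2)
    tag <- sprintf("%d", round(lv * 100))
    if (method == "delta") {
      out[[paste0("lo_", tag)]] <- out$estimate - z * out$se
      out[[paste0("hi_", tag)]] <- out$estimate + z * out$se
    } else {
      qs <- apply(sims, 2L, quantile, probs = c((1 - lv) / 2, 1 - (1 - lv) / 2))
      out[[paste0("lo_", tag)]] <- qs[1L, out$scenario]
      out[[paste0("hi_", tag)]] <- qs[2L, out$scenario]
    }
  }
  out$clipped <- FALSE
  if (clip) {
    rate_rows <- out$scenario != "difference"
    bound_cols <- c("estimate", grep("^(lo|hi)_", names(out), value = TRUE))
    for (cc in bound_cols) {
      clipped_here <- rate_rows & (out[[cc]] < 0 | out[[cc]] > 1)
      out$clipped <- out$clipped | clipped_here
      out[[cc]][rate_rows] <- clip01(out[[cc]][rate_rows])
    }
  }
  structure(out, class = c("heat_prediction", "data.frame"),
            metric = fit$metric, method = method, levels = levels)
}

#' @export
print.heat_prediction <- function(x, ...) {
  cat("Counterfactual seasonal predictions (metric:", attr(x, "metric"),
      "; CI method:", attr(x, "method"), ")\n")
  df <- as.data.frame(x)
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], round, 4)
  print(df, row.names = FALSE)
  invisible(x)
}

#' Plot counterfactual predictions with nested confidence bars
#'
#' @param x a [predict_rates()] result.
#' @param ... unused.
#' @export
plot.heat_prediction <- function(x, ...) {
  rows <- x[x$scenario != "difference", , drop = FALSE]
  lvls <- sort(attr(x, "levels"), decreasing = TRUE)
  xpos <- seq_len(nrow(rows))
  ylim <- range(rows[, grep("^(lo|hi)_", names(rows))], rows$estimate)
  plot(xpos, rows$estimate, pch = 19, xlim = c(0.5, nrow(rows) + 0.5),
       ylim = ylim, xaxt = "n", xlab = "", ylab = "predicted preterm rate",
       main = paste("Scenario predictions:", attr(x, "metric")))
  graphics::axis(1, at = xpos, labels = rows$scenario)
  for (i in seq_along(lvls)) {
    tag <- sprintf("%d", round(lvls[i] * 100))
    graphics::segments(xpos, rows[[paste0("lo_", tag)]],
                       xpos, rows[[paste0("hi_", tag)]], lwd = 2 * i)
  }
  invisible(x)
}
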