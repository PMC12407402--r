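#' Wet-bulb temperature from Stull's empirical approximation
#'
#' Approximates wet-bulb temperature from air temperature and relative
#' humidity using Stull's (2011) single-equation fit, which is accurate to
#' about 0.3-1 C inside its fitted envelope (roughly 5-99% relative humidity
#' and -20 to 50 C air temperature at standard pressure).
#'
#' @param t air temperature, degrees C (vectorised).
#' @param rh relative humidity, percent, in \[0, 100\].
#' @param warn warn when inputs fall outside the approximation's fitted
#'   envelope (default `TRUE`).
#' @return wet-bulb temperature, degrees C.
#' @examples
#' wet_bulb_stull(20, 50)
#' @export
wet_bulb_stull <- function(t, rh, warn = TRUE) {
  if (anyNA(t) || anyNA(rh)) stop("temperature and humidity must not contain NA")
  if (any(rh < 0 | rh > 100)) stop("relative humidity must lie in [0, 100]")
  if (warn && any(rh < 5 | t < -20 | t > 50)) {
    warning("some inputs fall outside the fitted envelope of Stull's approximation")
  }
  t * atan(0.151977 * sqrt(rh + 8.313659)) +
    atan(t + rh) - atan(rh - 1.676331) +
    0.00391838 * rh^1.5 * atan(0.023101 * rh) -
    4.686035
}

#' Append derived daily thermal fields to a weather table
#'
#' Adds the daily mean temperature `tmean_c = (tmax_c + tmin_c) / 2`, the
#' daily maximum wet-bulb temperature `wb_max_c` (Stull at `tmax_c` and the
#' daily humidity) and the daily average wet-bulb temperature `wb_mean_c`
#' (Stull at `tmean_c` and the daily humidity; relative humidity is a single
#' daily value at this granularity).
#'
#' @param weather a weather data frame with columns `location_id`, `date`,
#'   `tmax_c`, `tmin_c`, `rh_pct`.
#' @param warn passed to [wet_bulb_stull()].
#' @return `weather` with `tmean_c`, `wb_mean_c`, `wb_max_c` appended.
#' @export
derive_daily_fields <- function(weather, warn = FALSE) {
  assert_columns(weather, c("location_id", "date", "tmax_c", "tmin_c", "rh_pct"), "weather")
  if (any(weather$tmin_c > weather$tmax_c)) {
    stop("tmin_c exceeds tmax_c on some days")
  }
  bad <- which(weather$rh_pct < 0 | weather$rh_pct > 100)
  if (length(bad)) {
    stop("rh_pct outside [0, 100] at ", weather$location_id[bad[1]], " ",
         weather$date[bad[1]])
  }
  weather$tmean_c <- (weather$tmax_c + weather$tmin_c) / 2
  weather$wb_mean_c <- wet_bulb_stull(weather$tmean_c, weather$rh_pct, warn = warn)
  weather$wb_max_c <- wet_bulb_stull(weather$tmax_c, weather$rh_pct, warn = warn)
  weather
}

rolling_mean <- function(x, width) {
  as.numeric(stats::filter(x, rep(1 / width, width), sides = 1))
}

#' Excess Heat Factor per day
#'
#' Scores each day of a daily weather series with the Excess Heat Factor
#' (EHF): with `T3` the mean of daily mean temperature over the three days
#' ending today and `T30` the mean over the 30 days ending three days ago,
#' `EHF = (T3 - baseline) * max(1, T3 - T30)`. The significance term compares
#' recent heat against a long-term location reference; the acclimatisation
#' term compares it against the preceding month. The default baseline is the
#' long-term location mean of daily mean temperature over the full series;
#' `baseline = "p95"` uses the 95th percentile of daily means instead (the
#' operational heatwave-service convention). The first 32 days of each
#' location's series have insufficient history and are left unscored (`NA`).
#'
#' EHF carries squared-degree units; only its sign is used for heatwave
#' detection downstream.
#'
#' @param weather a weather data frame; `tmean_c` is derived on the fly if
#'   absent.
#' @param baseline `"mean"` (default) or `"p95"`.
#' @param long_term_mean optional named numeric vector of per-location
#'   baseline values (degrees C) overriding the computed baseline.
#' @return `weather` with columns `ehf` and `tmean_c` appended.
#' @export
excess_heat_factor <- function(weather, baseline = c("mean", "p95"),
                               long_term_mean = NULL) {
  baseline <- match.arg(baseline)
  assert_columns(weather, c("location_id", "date", "tmax_c", "tmin_c"), "weather")
  if (!"tmean_c" %in% names(weather)) {
    weather$tmean_c <- (weather$tmax_c + weather$tmin_c) / 2
  }
  weather$ehf <- NA_real_
  for (loc in unique(weather$location_id)) {
    idx <- which(weather$location_id == loc)
    idx <- idx[order(weather$date[idx])]
    check_gap_free(weather$date[idx], paste0("weather series for ", loc))
    x <- weather$tmean_c[idx]
    n <- length(x)
    if (n < 33L) {
      warning("series for ", loc, " shorter than the 33-day warm-up; all days unscored")
      next
    }
    ltm <- if (!is.null(long_term_mean)) {
      if (is.null(names(long_term_mean)) && length(long_term_mean) == 1L) {
        long_term_mean
      } else {
        if (!loc %in% names(long_term_mean)) stop("no long_term_mean supplied for ", loc)
        long_term_mean[[loc]]
      }
    } else if (baseline == "mean") {
      mean(x)
    } else {
      as.numeric(quantile(x, 0.95, type = 7))
    }
    t3 <- rolling_mean(x, 3L)
    ma30 <- rolling_mean(x, 30L)
    t30 <- c(rep(NA_real_, 3L), ma30[seq_len(n - 3L)]) # 30 days ending at d-3
    ehf <- (t3 - ltm) * pmax(1, t3 - t30)
    ehf[seq_len(min(32L, n))] <- NA_real_
    weather$ehf[idx] <- ehf
  }
  weather
}

#' Detect heatwave events from per-day EHF values
#'
#' A heatwave is a maximal run of three or more consecutive days with a
#' strictly positive Excess Heat Factor. Unscored (`NA`) days break runs.
#'
#' @param weather a weather data frame with columns `location_id`, `date`,
#'   `ehf` (as produced by [excess_heat_factor()]).
#' @return a data frame `location_id`, `start_date`, `end_date`, `duration`
#'   (days, inclusive), ordered by location then start date.
#' @export
detect_heatwaves <- function(weather) {
  assert_columns(weather, c("location_id", "date", "ehf"), "weather")
  out <- list()
  for (loc in unique(weather$location_id)) {
    idx <- which(weather$location_id == loc)
    idx <- idx[order(weather$date[idx])]
    pos <- !is.na(weather$ehf[idx]) & weather$ehf[idx] > 0
    r <- rle(pos)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    keep <- r$values & r$lengths >= 3L
    if (!any(keep)) next
    d <- weather$date[idx]
    out[[loc]] <- data.frame(
      location_id = loc,
      start_date = d[starts[keep]],
      end_date = d[ends[keep]],
      duration = r$lengths[keep],
      stringsAsFactors = FALSE
    )
  }
  if (!length(out)) {
    return(data.frame(location_id = character(), start_date = as_date(character()),
                      end_date = as_date(character()), duration = integer(),
                      stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
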