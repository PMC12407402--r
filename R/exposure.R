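#' Conception date from birth date and gestational age
#'
#' Conception is dated by subtracting the gestational age in completed weeks
#' from the birth date.
#'
#' @param birth_date `Date` vector.
#' @param gestational_weeks integer vector of completed weeks; values outside
#'   20-45 trigger a warning, `NA` is an error (such records are meant to be
#'   removed by [apply_exclusions()]).
#' @return `Date` vector of conception dates.
#' @examples
#' conception_date(as.Date("2005-10-08"), 40) # 2005-01-01
#' @export
conception_date <- function(birth_date, gestational_weeks) {
  birth_date <- as_date(birth_date)
  if (anyNA(gestational_weeks)) {
    stop("missing gestational age; exclude such records before dating conception")
  }
  out_of_range <- gestational_weeks < 20 | gestational_weeks > 45
  if (any(out_of_range & gestational_weeks != 0)) {
    warning("gestational age outside the plausible 20-45 week range")
  }
  birth_date - 7L * as.integer(gestational_weeks)
}

#' Trimester windows from a conception date
#'
#' Gestation is split into three fixed half-open day intervals from
#' conception: the first 12 weeks (84 days), the following 14 weeks (98 days)
#' and the following 13 weeks (91 days) -- 39 weeks (273 days) in total.
#' Each window is `[start, end)`.
#'
#' @param conception `Date` scalar.
#' @return a data frame with columns `trimester`, `start`, `end` (exclusive),
#'   `length_days`.
#' @export
trimester_windows <- function(conception) {
  conception <- as_date(conception)
  stopifnot(length(conception) == 1L, !is.na(conception))
  starts <- conception + c(0L, 84L, 182L)
  ends <- conception + c(84L, 182L, 273L)
  data.frame(trimester = 1:3, start = starts, end = ends,
             length_days = as.integer(ends - starts))
}

trimester_offsets <- function() c(0L, 84L, 182L, 273L)

#' Trimester lengths in days
#' @return the integer vector `c(84, 98, 91)`.
#' @export
trimester_lengths <- function() c(84L, 98L, 91L)

subset_window <- function(weather_loc, window) {
  start <- as_date(window[[1]]); end <- as_date(window[[2]])
  if (end <= start) stop("empty day window")
  sel <- weather_loc$date >= start & weather_loc$date < end
  got <- sum(sel)
  want <- as.integer(end - start)
  if (got != want) {
    stop("weather does not cover [", start, ", ", end, "): ",
         want - got, " day(s) missing")
  }
  weather_loc[sel, , drop = FALSE]
}

#' Count days per temperature band inside a window
#'
#' @param weather_loc weather rows for a single location (gap-free).
#' @param window a length-2 vector/list `(start, end)` with `end` exclusive.
#' @param field name of the daily column to band (e.g. `"tmax_c"`).
#' @param scheme a [band_scheme()].
#' @return named integer vector of day counts over all bands (including the
#'   omitted band); the counts sum to the window length.
#' @export
count_band_days <- function(weather_loc, window, field, scheme) {
  w <- subset_window(weather_loc, window)
  idx <- band_index(w[[field]], scheme)
  counts <- tabulate(idx, nbins = length(scheme$labels))
  setNames(as.integer(counts), scheme$labels)
}

#' Mean of a daily field inside a window
#'
#' @inheritParams count_band_days
#' @return the arithmetic mean over the window's days.
#' @export
trimester_mean <- function(weather_loc, window, field) {
  w <- subset_window(weather_loc, window)
  mean(w[[field]])
}

#' Count heatwave events attributed to a window
#'
#' Events are attributed to the window containing their start date, so an
#' event straddling two trimesters is counted exactly once.
#'
#' @param events a heatwave-event data frame ([detect_heatwaves()]).
#' @param window a length-2 vector/list `(start, end)` with `end` exclusive.
#' @return integer count.
#' @export
heatwave_count_in_window <- function(events, window) {
  if (nrow(events) == 0L) return(0L)
  start <- as_date(window[[1]]); end <- as_date(window[[2]])
  sum(events$start_date >= start & events$start_date < end)
}

# --- fast cohort-wide exposure construction -------------------------------

# Per-location cumulative summaries: row d+1 holds the cumulative value over
# days 1..d, so any [i, j) window aggregate is one row difference.
location_cumulatives <- function(weather_loc, metric, events_loc) {
  n <- nrow(weather_loc)
  cums <- vector("list", length(metric$terms))
  for (ti in seq_along(metric$terms)) {
    tm <- metric$terms[[ti]]
    if (tm$type == "bands") {
      idx <- band_index(weather_loc[[tm$field]], tm$scheme)
      nb <- length(tm$scheme$labels)
      ind <- matrix(0L, n, nb)
      ind[cbind(seq_len(n), idx)] <- 1L
      cums[[ti]] <- rbind(0L, apply(ind, 2, cumsum))
    } else if (tm$type == "mean") {
      cums[[ti]] <- matrix(c(0, cumsum(weather_loc[[tm$field]])), ncol = 1)
    } else if (tm$type == "hw_count") {
      starts <- integer(n)
      if (nrow(events_loc)) {
        pos <- match(events_loc$start_date, weather_loc$date)
        pos <- pos[!is.na(pos)]
        starts[pos] <- 1L
      }
      cums[[ti]] <- matrix(c(0L, cumsum(starts)), ncol = 1)
    } else {
      stop("unknown metric term type: ", tm$type)
    }
  }
  cums
}

needs_field <- function(metric, field) {
  any(vapply(metric$terms, function(tm) identical(tm$field, field), logical(1)))
}

ensure_metric_fields <- function(weather, metric, ehf_baseline = "mean") {
  if ((needs_field(metric, "wb_mean_c") || needs_field(metric, "wb_max_c")) &&
      !all(c("wb_mean_c", "wb_max_c") %in% names(weather))) {
    weather <- derive_daily_fields(weather)
  }
  if (needs_field(metric, "ehf") && !"ehf" %in% names(weather)) {
    weather <- excess_heat_factor(weather, baseline = ehf_baseline)
  }
  weather
}

#' Build per-birth, per-trimester exposure regressors
#'
#' Computes one exposure vector per birth under one heat metric. Exposure is
#' evaluated over the fixed 273-day schedule from conception for every birth,
#' including preterm births (so third-trimester exposure covers calendar days
#' after an early delivery; truncating at birth would make exposure
#' mechanically depend on the outcome). Set `truncate_at_birth = TRUE` to
#' instead stop counting the day after the actual birth date.
#'
#' Omitted (reference) band columns are materialised in the output, so the
#' per-trimester band counts sum exactly to 84/98/91 days; the
#' `"regressors"` attribute lists the non-omitted design columns and the
#' `"omitted"` attribute the reference columns.
#'
#' @param births a birth-record data frame with `birth_id`, `location_id`,
#'   and either a `conception_date` column or `birth_date` +
#'   `gestational_weeks` from which it is derived.
#' @param weather a daily weather data frame covering every pregnancy's
#'   273-day schedule at its location; derived fields (wet bulb, EHF) are
#'   computed on the fly when the metric needs them.
#' @param metric a [heat_metric()] object or metric name.
#' @param truncate_at_birth stop exposure the day after birth (default
#'   `FALSE`, the fixed-schedule convention).
#' @param ehf_baseline passed to [excess_heat_factor()] when EHF is derived.
#' @return a data frame: `birth_id` plus one column per regressor, with
#'   attributes `metric`, `regressors`, `omitted`.
#' @export
build_exposures <- function(births, weather, metric,
                            truncate_at_birth = FALSE, ehf_baseline = "mean") {
  metric <- as_heat_metric(metric)
  assert_columns(births, c("birth_id", "location_id"), "births")
  if (!"conception_date" %in% names(births)) {
    assert_columns(births, c("birth_date", "gestational_weeks"), "births")
    births$conception_date <- conception_date(births$birth_date,
                                              births$gestational_weeks)
  }
  births$conception_date <- as_date(births$conception_date)
  weather <- ensure_metric_fields(weather, metric, ehf_baseline)
  events <- if (needs_field(metric, "ehf")) detect_heatwaves(weather) else
    data.frame(location_id = character(), start_date = as_date(character()))

  all_cols <- unlist(lapply(metric$terms, function(tm) {
    unlist(lapply(1:3, function(k) term_colnames(tm, k)))
  }))
  out <- matrix(NA_real_, nrow(births), length(all_cols),
                dimnames = list(NULL, all_cols))

  offs <- trimester_offsets()
  for (loc in unique(births$location_id)) {
    bi <- which(births$location_id == loc)
    wi <- which(weather$location_id == loc)
    if (!length(wi)) {
      stop("no weather for location ", loc, "; affected birth ids: ",
           paste(head(births$birth_id[bi], 5L), collapse = ", "))
    }
    wl <- weather[wi, , drop = FALSE]
    wl <- wl[order(wl$date), , drop = FALSE]
    check_gap_free(wl$date, paste0("weather series for ", loc))
    day1 <- wl$date[1]
    nday <- nrow(wl)
    start_idx <- as.integer(births$conception_date[bi] - day1) + 1L
    bad <- start_idx < 1L | start_idx + 273L > nday + 1L
    if (any(bad)) {
      stop("weather at ", loc, " does not cover the 273-day schedule for ",
           "birth id(s): ", paste(head(births$birth_id[bi][bad], 5L), collapse = ", "))
    }
    cums <- location_cumulatives(wl, metric, events[events$location_id == loc, , drop = FALSE])
    # row indices into the (nday + 1)-row cumulative matrices
    bounds <- outer(start_idx, offs, `+`) # births x 4
    if (truncate_at_birth) {
      assert_columns(births, "birth_date", "births")
      stop_idx <- pmin(as.integer(births$birth_date[bi] - day1) + 2L,
                       bounds[, 4L])
      for (k in 2:4) bounds[, k] <- pmin(bounds[, k], pmax(stop_idx, bounds[, k - 1L]))
    }
    col0 <- 0L
    for (ti in seq_along(metric$terms)) {
      tm <- metric$terms[[ti]]
      cm <- cums[[ti]]
      nb <- ncol(cm)
      for (k in 1:3) {
        vals <- cm[bounds[, k + 1L], , drop = FALSE] - cm[bounds[, k], , drop = FALSE]
        if (tm$type == "mean") {
          vals <- vals / (bounds[, k + 1L] - bounds[, k])
        }
        out[bi, col0 + seq_len(nb) + (k - 1L) * nb] <- vals
      }
      col0 <- col0 + 3L * nb
    }
  }
  res <- data.frame(birth_id = births$birth_id, out, check.names = FALSE,
                    stringsAsFactors = FALSE)
  attr(res, "metric") <- metric$name
  attr(res, "omitted") <- metric_omitted(metric)
  attr(res, "regressors") <- setdiff(all_cols, metric_omitted(metric))
  res
}

#' Combine exposure tables from several metrics into one term-grouped table
#'
#' Joins exposure tables by `birth_id` so that several metric term-groups can
#' enter one model. Duplicate regressor columns (e.g. the shared maximum
#' bands of `benchmark` and `max_and_min`) keep their first occurrence.
#'
#' @param exposure_list a list of [build_exposures()] outputs.
#' @return a combined exposure data frame with merged attributes.
#' @export
combine_exposures <- function(exposure_list) {
  stopifnot(length(exposure_list) >= 1L)
  base <- exposure_list[[1L]]
  omitted <- attr(base, "omitted")
  regs <- attr(base, "regressors")
  metric <- attr(base, "metric")
  for (e in exposure_list[-1L]) {
    if (!identical(e$birth_id, base$birth_id)) {
      e <- e[match(base$birth_id, e$birth_id), , drop = FALSE]
      if (anyNA(e$birth_id)) stop("exposure tables cover different birth ids")
    }
    new_cols <- setdiff(names(e), c("birth_id", names(base)))
    base <- cbind(base, e[, new_cols, drop = FALSE])
    omitted <- union(omitted, attr(e, "omitted"))
    regs <- union(regs, setdiff(attr(e, "regressors"), omitted))
    metric <- paste(metric, attr(e, "metric"), sep = "+")
  }
  attr(base, "metric") <- metric
  attr(base, "omitted") <- omitted
  attr(base, "regressors") <- setdiff(regs, omitted)
  base
}
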