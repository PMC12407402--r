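test_that("conception dating is exact calendar arithmetic", {
  expect_equal(conception_date(as.Date("2005-10-08"), 40), as.Date("2005-01-01"))
  expect_equal(conception_date(as.Date("2005-10-08"), 0), as.Date("2005-10-08"))
  set.seed(2)
  d <- as.Date("2000-01-01") + sample(4000, 25)
  g <- sample(20:45, 25, replace = TRUE)
  expect_equal(conception_date(d, g) + 7L * g, d)
  expect_warning(conception_date(as.Date("2005-01-01"), 10), "plausible")
  expect_error(conception_date(as.Date("2005-01-01"), NA), "missing")
})

test_that("trimester windows are the fixed 84/98/91-day half-open intervals", {
  w <- trimester_windows(as.Date("2005-01-01"))
  expect_equal(w$length_days, c(84L, 98L, 91L))
  expect_equal(sum(w$length_days), 273L)
  expect_equal(w$start[1], as.Date("2005-01-01"))
  expect_equal(w$end[1], as.Date("2005-03-26"))
  expect_equal(w$start[2], w$end[1])
  expect_equal(w$start[3], w$end[2])
  # disjoint and ordered for arbitrary conception dates
  for (c0 in as.Date(c("1999-12-31", "2004-02-29", "2010-07-15"))) {
    ww <- trimester_windows(c0)
    expect_true(all(ww$start < ww$end))
    expect_true(all(ww$end[-3] == ww$start[-1]))
  }
})

test_that("band day counts follow the half-open convention and conserve days", {
  sch <- heatbands:::scheme_tmax()
  w <- toy_weather("x", "2001-01-01", list(tmax = rep(32, 84)))
  cts <- count_band_days(w, c(as.Date("2001-01-01"), as.Date("2001-03-26")),
                         "tmax_c", sch)
  expect_equal(unname(cts["30_35"]), 84L)
  expect_equal(sum(cts), 84L)

  w2 <- toy_weather("x", "2001-01-01", list(tmax = c(18, 22, 27, 33, 41)))
  cts2 <- count_band_days(w2, c(as.Date("2001-01-01"), as.Date("2001-01-06")),
                          "tmax_c", sch)
  expect_equal(unname(cts2[c("lt20", "20_25", "25_30", "30_35", "35_40", "ge40")]),
               c(1L, 1L, 1L, 1L, 0L, 1L))

  # 25.0 falls in [25, 30), not [20, 25)
  w3 <- toy_weather("x", "2001-01-01", list(tmax = 25.0))
  cts3 <- count_band_days(w3, c(as.Date("2001-01-01"), as.Date("2001-01-02")),
                          "tmax_c", sch)
  expect_equal(unname(cts3["25_30"]), 1L)
  expect_equal(unname(cts3["20_25"]), 0L)

  expect_error(count_band_days(w3, c(as.Date("2001-01-01"), as.Date("2001-01-05")),
                               "tmax_c", sch), "does not cover")
})

test_that("trimester means are exact and translation-equivariant", {
  w <- toy_weather("x", "2001-01-01", list(tmax = c(30, 32, 34)))
  win <- c(as.Date("2001-01-01"), as.Date("2001-01-04"))
  expect_equal(trimester_mean(w, win, "tmax_c"), 32)
  w$tmax_c <- w$tmax_c + 2.5
  expect_equal(trimester_mean(w, win, "tmax_c"), 34.5)
})

test_that("heatwave events are attributed to windows by start date", {
  ev <- data.frame(location_id = "x",
                   start_date = as.Date(c("2001-02-01", "2001-03-25")),
                   end_date = as.Date(c("2001-02-04", "2001-03-30")),
                   duration = c(4L, 6L))
  w <- trimester_windows(as.Date("2001-01-01"))
  w1 <- c(w$start[1], w$end[1]); w2 <- c(w$start[2], w$end[2])
  # 2001-03-25 is W1's last day: the straddling event counts once, in W1
  expect_equal(heatwave_count_in_window(ev, w1), 2L)
  expect_equal(heatwave_count_in_window(ev, w2), 0L)
  expect_equal(heatwave_count_in_window(ev[0, ], w1), 0L)
})

test_that("cohort exposure vectors equal a hand tally on constructed weather", {
  # 84 cool days, 98 warm days, 91 hot days from conception
  vals <- list(tmax = c(rep(18, 84), rep(32, 98), rep(41, 91)),
               tmin = c(rep(8, 84), rep(22, 98), rep(26, 91)))
  w <- toy_weather("L", "2001-01-01", vals)
  births <- data.frame(birth_id = "b1", location_id = "L",
                       conception_date = as.Date("2001-01-01"),
                       birth_date = as.Date("2001-01-01") + 273,
                       gestational_weeks = 39L)
  ex <- build_exposures(births, w, "max_and_min")
  expect_equal(ex$max_lt20_t1, 84)
  expect_equal(ex$max_30_35_t2, 98)
  expect_equal(ex$max_ge40_t3, 91)
  expect_equal(ex$min_5_10_t1, 84)
  expect_equal(ex$min_20_25_t2, 98)
  expect_equal(ex$min_ge25_t3, 91)
  expect_equal(sum(ex[grep("^max_.*_t1$", names(ex))]), 84)
  ex_avg <- build_exposures(births, w, "trimester_average")
  expect_equal(ex_avg$avg_tmax_t1, 18)
  expect_equal(ex_avg$avg_tmax_t3, 41)
})

test_that("band counts conserve trimester lengths for every banded metric", {
  sw <- small_world()
  dgp <- cohort_dgp(60, conception_range = sw$conception_range)
  births <- gen_cohort(sw$weather, dgp, seed = 12)$births
  lens <- trimester_lengths()
  for (m in c("benchmark", "max_and_min", "wet_bulb")) {
    ex <- build_exposures(births, sw$weather, m)
    spec <- heat_metric(m)
    for (tm in spec$terms) {
      for (k in 1:3) {
        cols <- paste0(tm$prefix, "_", tm$scheme$labels, "_t", k)
        expect_equal(unname(rowSums(ex[, cols])), rep(lens[k], nrow(ex)))
      }
    }
    expect_true(all(attr(ex, "omitted") %in% names(ex)))
    expect_false(any(attr(ex, "omitted") %in% attr(ex, "regressors")))
  }
})

test_that("exposure follows the fixed 273-day schedule even for preterm births", {
  sw <- small_world()
  births <- data.frame(birth_id = "p1",
                       location_id = sw$locations$location_id[1],
                       birth_date = as.Date("2002-07-30"),
                       gestational_weeks = 30L) # birth at 210 days
  ex <- build_exposures(births, sw$weather, "benchmark")
  t3_cols <- grep("_t3$", names(ex), value = TRUE)
  expect_equal(sum(ex[, t3_cols]), 91) # third window still fully scored
  ex_tr <- build_exposures(births, sw$weather, "benchmark",
                           truncate_at_birth = TRUE)
  expect_lt(sum(ex_tr[, t3_cols]), 91)
})

test_that("regressor layouts match the metric definitions", {
  expect_length(metric_regressors("benchmark"), 15)
  expect_length(metric_regressors("max_and_min"), 30)
  expect_length(metric_regressors("wet_bulb"), 27)
  expect_length(metric_regressors("trimester_average"), 3)
  expect_length(metric_regressors("heatwave_count"), 3)
  expect_equal(sort(metric_omitted("benchmark")),
               sort(paste0("max_25_30_t", 1:3)))
  expect_equal(sort(metric_omitted("wet_bulb")),
               sort(c(paste0("wbavg_15_20_t", 1:3), paste0("wbmax_20_25_t", 1:3))))
})

test_that("exposure construction is deterministic and validates coverage", {
  sw <- small_world()
  dgp <- cohort_dgp(40, conception_range = sw$conception_range)
  births <- gen_cohort(sw$weather, dgp, seed = 3)$births
  e1 <- build_exposures(births, sw$weather, "max_and_min")
  e2 <- build_exposures(births, sw$weather, "max_and_min")
  expect_identical(e1, e2)
  bad <- births
  bad$conception_date[1] <- as.Date("1990-01-01")
  expect_error(build_exposures(bad, sw$weather, "benchmark"),
               "does not cover.*birth id")
})

test_that("combining metric exposure tables preserves groups and omissions", {
  sw <- small_world()
  dgp <- cohort_dgp(30, conception_range = sw$conception_range)
  births <- gen_cohort(sw$weather, dgp, seed = 8)$births
  combo <- combine_exposures(list(
    build_exposures(births, sw$weather, "max_and_min"),
    build_exposures(births, sw$weather, "heatwave_count")
  ))
  expect_length(attr(combo, "regressors"), 33)
  expect_true(all(paste0("hw_count_t", 1:3) %in% names(combo)))
})
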