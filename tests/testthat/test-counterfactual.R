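test_that("a single noise-free year is its own climatology", {
  p <- climate_zone_params("tropical", noise_sd_max = 0, noise_sd_range = 0,
                           rh_noise_sd = 0)
  w <- gen_weather(p, "x", as.Date(c("2001-01-01", "2001-12-31")), seed = 1)
  prof <- day_of_year_climatology(w)
  expect_equal(nrow(prof), 366) # Feb 29 filled from Feb 28
  back <- prof[match(format(w$date, "%m-%d"), prof$month_day), ]
  expect_equal(back$tmax_c, w$tmax_c, tolerance = 1e-12)
  expect_equal(prof$tmax_c[prof$month_day == "02-29"],
               prof$tmax_c[prof$month_day == "02-28"])
})

test_that("the climatology of two offset years is their midpoint", {
  p <- climate_zone_params("arid", noise_sd_max = 0, noise_sd_range = 0,
                           rh_noise_sd = 0)
  w1 <- gen_weather(p, "x", as.Date(c("2001-01-01", "2001-12-31")), seed = 1)
  w2 <- w1
  w2$date <- w2$date + 365
  w2$tmax_c <- w2$tmax_c + 1
  w2$tmin_c <- w2$tmin_c + 1
  prof <- day_of_year_climatology(rbind(w1, w2))
  idx <- match(format(w1$date, "%m-%d"), prof$month_day)
  expect_equal(prof$tmax_c[idx], w1$tmax_c + 0.5, tolerance = 1e-10)
  # derived fields recomputed from averaged base fields
  expect_equal(prof$wb_max_c, wet_bulb_stull(prof$tmax_c, prof$rh_pct, warn = FALSE))
})

test_that("incomplete years are excluded with a warning", {
  p <- climate_zone_params("tropical")
  w <- gen_weather(p, "x", as.Date(c("2001-01-01", "2002-03-01")), seed = 2)
  expect_warning(prof <- day_of_year_climatology(w), "incomplete")
  expect_equal(nrow(prof), 366)
  w_short <- w[format(w$date, "%Y") == "2002", ]
  expect_error(day_of_year_climatology(w_short), "complete reference year")
})

test_that("a flat climatology yields identical hottest and coolest exposures", {
  prof_w <- toy_weather("x", "2004-01-01",
                        list(tmax = rep(30, 366 + 365), tmin = rep(22, 731),
                             rh = rep(60, 731)))
  prof <- day_of_year_climatology(prof_w)
  births <- data.frame(birth_id = c("b1", "b2"), location_id = "x")
  hot <- scenario_exposure(prof, "hottest9", "benchmark", births)
  cool <- scenario_exposure(prof, "coolest9", "benchmark", births)
  expect_equal(hot[, -1], cool[, -1], ignore_attr = TRUE)
  # conservation carries over to scenario vectors
  for (k in 1:3) {
    cols <- grep(paste0("^max_.*_t", k, "$"), names(hot), value = TRUE)
    expect_equal(unname(rowSums(hot[, cols])), rep(trimester_lengths()[k], 2))
  }
})

test_that("tropical scenarios order exposure as hottest >= coolest", {
  sw <- small_world()
  prof <- suppressWarnings(day_of_year_climatology(sw$weather))
  births <- data.frame(birth_id = "b1",
                       location_id = sw$locations$location_id[1])
  hot <- scenario_exposure(prof, "hottest9", "trimester_average", births)
  cool <- scenario_exposure(prof, "coolest9", "trimester_average", births)
  expect_gt(mean(as.numeric(hot[, -1])), mean(as.numeric(cool[, -1])))
  expect_error(scenario_exposure(prof, "warm", "benchmark", births), "scenario")
})

test_that("zero heat coefficients give degenerate scenario predictions", {
  sw <- small_world()
  dgp <- cohort_dgp(600, conception_range = sw$conception_range)
  births <- gen_cohort(sw$weather, dgp, seed = 61)$births
  ex <- build_exposures(births, sw$weather, "trimester_average")
  fit <- suppressWarnings(fe_lpm(births, ex, sw$clusters))
  fit$coefficients[fit$heat_terms] <- 0
  fit$vcov[fit$heat_terms, fit$heat_terms] <- 0
  prof <- suppressWarnings(day_of_year_climatology(sw$weather))
  scen <- list(
    hottest9 = scenario_exposure(prof, "hottest9", "trimester_average", births),
    coolest9 = scenario_exposure(prof, "coolest9", "trimester_average", births)
  )
  pr <- predict_rates(fit, ex, scen)
  expect_equal(pr$estimate[pr$scenario == "hottest9"], fit$ybar)
  expect_equal(pr$estimate[pr$scenario == "coolest9"], fit$ybar)
  expect_equal(pr$estimate[pr$scenario == "difference"], 0)
  expect_equal(pr$lo_95[pr$scenario == "difference"], 0)
})

test_that("predictions are the exact heat-term contrast and nest their intervals", {
  sw <- small_world()
  dgp <- cohort_dgp(2000, metric = "benchmark",
                    band_effects = c(max_ge40_t3 = 0.004, max_lt20_t2 = -0.003),
                    conception_range = sw$conception_range)
  births <- gen_cohort(sw$weather, dgp, seed = 63)$births
  ex <- build_exposures(births, sw$weather, "benchmark")
  fit <- suppressWarnings(fe_lpm(births, ex, sw$clusters))
  prof <- suppressWarnings(day_of_year_climatology(sw$weather))
  scen <- list(
    hottest9 = scenario_exposure(prof, "hottest9", "benchmark", births),
    coolest9 = scenario_exposure(prof, "coolest9", "benchmark", births)
  )
  pr <- predict_rates(fit, ex, scen, clip = FALSE)

  # hand-computed contrast: FE and covariate terms cancel by construction
  terms <- fit$heat_terms
  a_hot <- colMeans(as.matrix(scen$hottest9[match(ex$birth_id, scen$hottest9$birth_id), terms]) -
                      as.matrix(ex[, terms]))
  a_cool <- colMeans(as.matrix(scen$coolest9[match(ex$birth_id, scen$coolest9$birth_id), terms]) -
                       as.matrix(ex[, terms]))
  expect_equal(pr$estimate[pr$scenario == "difference"],
               sum((a_hot - a_cool) * fit$coefficients[terms]), tolerance = 1e-12)
  expect_equal(pr$estimate[pr$scenario == "hottest9"] -
                 pr$estimate[pr$scenario == "coolest9"],
               pr$estimate[pr$scenario == "difference"], tolerance = 1e-12)

  # CI nesting: 68 within 80 within 95
  for (i in seq_len(nrow(pr))) {
    expect_gte(pr$lo_68[i], pr$lo_80[i])
    expect_gte(pr$lo_80[i], pr$lo_95[i])
    expect_lte(pr$hi_68[i], pr$hi_80[i])
    expect_lte(pr$hi_80[i], pr$hi_95[i])
  }

  # simulation CIs agree with delta-method CIs
  set.seed(99)
  pr_sim <- predict_rates(fit, ex, scen, method = "simulation",
                          n_draws = 10000, clip = FALSE)
  hw_d <- pr$hi_95 - pr$lo_95
  hw_s <- pr_sim$hi_95 - pr_sim$lo_95
  expect_lt(max(abs(hw_s - hw_d) / hw_d), 0.1)
})

test_that("a planted DGP's predicted difference tracks the analytic truth", {
  sw <- study_world()
  eff <- planted_truth()
  dgp <- cohort_dgp(8000, metric = "max_and_min", band_effects = eff,
                    conception_range = sw$conception_range)
  g <- gen_cohort(sw$weather, dgp, seed = 67)
  ex <- build_exposures(g$births, sw$weather, "max_and_min")
  fit <- fe_lpm(g$births, ex, sw$clusters)
  prof <- suppressWarnings(day_of_year_climatology(sw$weather))
  scen <- list(
    hottest9 = scenario_exposure(prof, "hottest9", "max_and_min", g$births),
    coolest9 = scenario_exposure(prof, "coolest9", "max_and_min", g$births)
  )
  pr <- predict_rates(fit, ex, scen, clip = FALSE)
  # truth: apply the DGP coefficients to the same scenario contrast
  terms <- names(eff)
  a_diff <- colMeans(as.matrix(scen$hottest9[match(ex$birth_id, scen$hottest9$birth_id), terms]) -
                       as.matrix(scen$coolest9[match(ex$birth_id, scen$coolest9$birth_id), terms]))
  true_diff <- sum(a_diff * eff)
  est <- pr$estimate[pr$scenario == "difference"]
  se <- pr$se[pr$scenario == "difference"]
  expect_lt(abs(est - true_diff), 4 * se)
})
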