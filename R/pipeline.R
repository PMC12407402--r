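#' Default end-to-end pipeline configuration
#'
#' A complete configuration for [run_pipeline()]: two climate zones with a
#' handful of locations each, roughly a decade of weather, a cohort whose
#' preterm risk loads on maximum- and minimum-temperature bands (the
#' `max_and_min` data-generating process), all five candidate metrics, the
#' 5% screening level and the hottest/coolest-9-months scenario block.
#' Any element can be overridden before running; [read_pipeline_config()]
#' loads the same structure from a YAML file.
#'
#' @param n_births cohort size (default 3000).
#' @return a nested configuration list.
#' @export
default_config <- function(n_births = 3000) {
  list(
    seed = 1L,
    zones = list(
      tropical = list(n_locations = 4L, params = list()),
      arid = list(n_locations = 4L, params = list())
    ),
    weather = list(start = "2000-06-01", end = "2009-12-31"),
    cohort = list(
      n_births = n_births,
      baseline_preterm_rate = 0.10,
      metric = "max_and_min",
      band_effects = list(
        min_ge25_t2 = 0.005, min_ge25_t1 = 0.005, min_lt5_t1 = -0.004,
        min_5_10_t3 = -0.003, max_35_40_t3 = 0.002, max_ge40_t3 = 0.003,
        max_lt20_t2 = -0.002
      ),
      covariate_effects = list(first_pregnancy = 0.01, aboriginal = 0.02),
      conception_start = "2001-03-01",
      conception_end = "2008-09-30",
      link = "linear"
    ),
    metrics = c("benchmark", "trimester_average", "heatwave_count",
                "max_and_min", "wet_bulb"),
    cluster_max_diameter_miles = 50,
    selection_alpha = 0.05,
    scenario = list(reference_year = 2005L, levels = c(0.68, 0.80, 0.95)),
    strata = NULL
  )
}

#' @rdname default_config
#' @param path YAML file path.
#' @export
read_pipeline_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  base <- default_config()
  unknown <- setdiff(names(cfg), names(base))
  if (length(unknown)) stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  utils::modifyList(base, cfg)
}

#' Run the full simulation-to-prediction pipeline
#'
#' Orchestrates: simulate weather for the configured zones; derive thermal
#' fields, EHF and heatwaves; cluster locations at the configured diameter;
#' generate the synthetic cohort; apply the exclusion filters; build
#' exposures for every configured metric; fit the fixed-effects linear
#' probability model per metric; run the two-stage metric selection; and
#' produce hottest/coolest-9-months counterfactual predictions for every
#' fitted metric. When stratification filters are configured (e.g.
#' `list(aboriginal = 1)` or `list(zone = "tropical")`), the fit/select
#' stages are re-run on each stratum.
#'
#' Identical `(config, seed)` give identical outputs; each stage draws from
#' its own seed substream (see [stage_seed()]).
#'
#' @param config a configuration list ([default_config()]).
#' @param seed overrides `config$seed` when given.
#' @param out_dir optional directory; when given, all tabular artifacts are
#'   written as CSV, the selection report and predictions also as JSON, and
#'   the fully-resolved config as YAML.
#' @return (invisibly) a list with `locations`, `weather`, `clusters`,
#'   `events`, `births`, `truth`, `exclusion_report`, `exposures`, `fits`,
#'   `selection`, `climatology`, `predictions`, and `strata` results.
#' @export
run_pipeline <- function(config = default_config(), seed = NULL, out_dir = NULL) {
  cfg <- config
  seed <- as.integer(seed %||% cfg$seed)

  locations <- nt_locations(
    n_tropical = cfg$zones$tropical$n_locations %||% 0L,
    n_arid = cfg$zones$arid$n_locations %||% 0L,
    seed = stage_seed(seed, "locations")
  )
  dates <- as.Date(c(cfg$weather$start, cfg$weather$end))
  wseed <- stage_seed(seed, "weather")
  weather <- do.call(rbind, lapply(c("tropical", "arid"), function(z) {
    locs <- locations$location_id[locations$zone == z]
    if (!length(locs)) return(NULL)
    params <- do.call(climate_zone_params, c(list(zone = z), cfg$zones[[z]]$params))
    gen_weather(params, locs, dates, seed = wseed + match(z, c("tropical", "arid")))
  }))
  weather <- derive_daily_fields(weather)
  weather <- excess_heat_factor(weather)
  events <- detect_heatwaves(weather)
  clusters <- cluster_max_diameter(locations,
                                   max_diameter = cfg$cluster_max_diameter_miles %||% 50)

  dgp <- cohort_dgp(
    n_births = cfg$cohort$n_births,
    baseline_preterm_rate = cfg$cohort$baseline_preterm_rate %||% 0.10,
    metric = cfg$cohort$metric %||% "max_and_min",
    band_effects = unlist(cfg$cohort$band_effects),
    covariate_effects = unlist(cfg$cohort$covariate_effects),
    conception_range = as.Date(c(cfg$cohort$conception_start,
                                 cfg$cohort$conception_end)),
    link = cfg$cohort$link %||% "linear"
  )
  gen <- gen_cohort(weather, dgp, seed = stage_seed(seed, "cohort"))
  excl <- apply_exclusions(gen$births)
  births <- excl$births

  metrics <- cfg$metrics
  exposures <- lapply(setNames(metrics, metrics), function(m) {
    build_exposures(births, weather, m)
  })
  fit_all <- function(b) {
    lapply(setNames(metrics, metrics), function(m) {
      ex <- exposures[[m]]
      ex <- ex[ex$birth_id %in% b$birth_id, , drop = FALSE]
      for (a in c("metric", "omitted", "regressors")) {
        attr(ex, a) <- attr(exposures[[m]], a)
      }
      fe_lpm(b, ex, clusters, outcome = "preterm")
    })
  }
  fits <- fit_all(births)
  selection <- rank_and_select(fits, alpha = cfg$selection_alpha %||% 0.05)

  climatology <- day_of_year_climatology(weather)
  ref_year <- cfg$scenario$reference_year %||% 2005L
  predictions <- lapply(setNames(metrics, metrics), function(m) {
    fit <- fits[[m]]
    scen <- lapply(setNames(c("hottest9", "coolest9"), c("hottest9", "coolest9")),
                   function(s) scenario_exposure(climatology, s, m, births,
                                                 reference_year = ref_year))
    predict_rates(fit, exposures[[m]], scen,
                  levels = cfg$scenario$levels %||% c(0.68, 0.80, 0.95))
  })

  strata_res <- NULL
  if (length(cfg$strata)) {
    strata_res <- lapply(cfg$strata, function(filt) {
      b <- births
      for (nm in names(filt)) {
        if (nm == "zone") {
          locs <- locations$location_id[locations$zone == filt[[nm]]]
          b <- b[b$location_id %in% locs, , drop = FALSE]
        } else {
          b <- b[b[[nm]] == filt[[nm]], , drop = FALSE]
        }
      }
      f <- fit_all(b)
      list(filter = filt, n = nrow(b), fits = f,
           selection = rank_and_select(f, alpha = cfg$selection_alpha %||% 0.05))
    })
  }

  res <- list(locations = locations, weather = weather, clusters = clusters,
              events = events, births = births, truth = gen$truth,
              exclusion_report = excl$report, exposures = exposures,
              fits = fits, selection = selection, climatology = climatology,
              predictions = predictions, strata = strata_res,
              config = cfg, seed = seed)
  if (!is.null(out_dir)) write_pipeline_outputs(res, out_dir)
  invisible(res)
}

write_pipeline_outputs <- function(res, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(...) file.path(out_dir, ...)
  yaml::write_yaml(res$config, p("config.yaml"))
  write.csv(res$locations, p("locations.csv"), row.names = FALSE)
  write.csv(as.data.frame(res$clusters), p("clusters.csv"), row.names = FALSE)
  write_weather_csv(res$weather, p("weather.csv"))
  write.csv(res$events, p("heatwaves.csv"), row.names = FALSE)
  write_births_csv(res$births, p("births.csv"))
  write_truth(res$truth, p("truth.json"))
  jsonlite::write_json(as.list(res$exclusion_report), p("exclusions.json"),
                       auto_unbox = TRUE)
  for (m in names(res$exposures)) {
    write_exposures_csv(res$exposures[[m]], p(paste0("exposures_", m, ".csv")))
    write.csv(coef_table(res$fits[[m]]), p(paste0("coefficients_", m, ".csv")),
              row.names = FALSE)
    write.csv(as.data.frame(res$predictions[[m]]),
              p(paste0("prediction_", m, ".csv")), row.names = FALSE)
  }
  sel <- as.data.frame(res$selection)
  write.csv(sel, p("selection_report.csv"), row.names = FALSE)
  jsonlite::write_json(list(preferred = attr(res$selection, "preferred"),
                            rationale = attr(res$selection, "rationale")),
                       p("selection.json"), auto_unbox = TRUE)
  invisible(out_dir)
}
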