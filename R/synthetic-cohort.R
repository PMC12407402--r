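#' Specify the cohort data-generating process
#'
#' Describes how synthetic birth records and their preterm outcome are
#' generated. The latent preterm probability is linear in the per-trimester
#' exposure regressors of a declared heat metric (matching the estimated
#' model family, so parameter recovery is an exact identification check):
#' `p_i = baseline + sum(band_effects * exposure_i) + covariate_effects * X_i`,
#' clipped to \[0, 1\]; a logistic link is available for robustness
#' experiments. Band-effect names must resolve against the metric's
#' regressor names (e.g. `max_35_40_t3`), so the simulation truth is
#' recoverable by the estimator.
#'
#' @param n_births cohort size.
#' @param baseline_preterm_rate baseline probability at zero exposure effects
#'   (default 0.10).
#' @param metric the declared heat metric (name or [heat_metric()]).
#' @param band_effects named numeric vector: probability change per exposure
#'   unit (per day for band counts and heatwave counts, per degree for
#'   trimester means); default none.
#' @param covariate_effects named numeric vector over
#'   `first_pregnancy`, `aboriginal`, `age_lt20`, `age_20_24`, `age_30_34`,
#'   `age_35_39`, `age_ge40`; default none.
#' @param conception_range length-2 `Date` vector; conception dates are
#'   sampled uniformly over it (sampling by conception date avoids
#'   fixed-cohort bias).
#' @param link `"linear"` (default) or `"logistic"`.
#' @param center_exposures apply band effects to exposure regressors centred
#'   within location x conception-month cells (default `TRUE`): heat affects
#'   risk through deviations from the local seasonal norm, the cell-level
#'   shift is absorbed by the model's fixed effects,
#'   `baseline_preterm_rate` stays the cohort rate and clipping is rare. The
#'   slope coefficients are unchanged either way. Set `FALSE` for the raw
#'   intercept parameterisation.
#' @param gestation_preterm,gestation_term integer week ranges for preterm
#'   and term gestational length.
#' @param birthweight list with `mean`, `sd`, `preterm_shift`, and optional
#'   named `effects` on exposure regressors, for the analogous continuous
#'   outcome.
#' @return an object of class `cohort_dgp`.
#' @export
cohort_dgp <- function(n_births,
                       baseline_preterm_rate = 0.10,
                       metric = "max_and_min",
                       band_effects = NULL,
                       covariate_effects = NULL,
                       conception_range = as.Date(c("2001-03-01", "2008-09-30")),
                       link = c("linear", "logistic"),
                       center_exposures = TRUE,
                       gestation_preterm = 28:36,
                       gestation_term = 37:42,
                       birthweight = list(mean = 3400, sd = 450,
                                          preterm_shift = -600, effects = NULL)) {
  link <- match.arg(link)
  metric <- as_heat_metric(metric)
  stopifnot(n_births >= 0, baseline_preterm_rate >= 0, baseline_preterm_rate <= 1)
  regs <- metric_regressors(metric, include_omitted = TRUE)
  if (!is.null(band_effects)) {
    bad <- setdiff(names(band_effects), regs)
    if (length(bad)) {
      stop("band_effects name(s) not resolvable against metric '", metric$name,
           "': ", paste(bad, collapse = ", "))
    }
  }
  cov_names <- c("first_pregnancy", "aboriginal",
                 paste0("age_", setdiff(age_band_levels(), "25_29")))
  if (!is.null(covariate_effects)) {
    bad <- setdiff(names(covariate_effects), cov_names)
    if (length(bad)) stop("unknown covariate effect(s): ", paste(bad, collapse = ", "))
  }
  conception_range <- as_date(conception_range)
  stopifnot(length(conception_range) == 2L,
            conception_range[1] <= conception_range[2])
  if (any(gestation_preterm >= 37)) stop("preterm gestation must be < 37 weeks")
  if (any(gestation_term < 37)) stop("term gestation must be >= 37 weeks")
  structure(list(
    n_births = n_births,
    baseline_preterm_rate = baseline_preterm_rate,
    metric = metric,
    band_effects = band_effects,
    covariate_effects = covariate_effects,
    conception_range = conception_range,
    link = link,
    center_exposures = center_exposures,
    gestation_preterm = gestation_preterm,
    gestation_term = gestation_term,
    birthweight = birthweight
  ), class = "cohort_dgp")
}

empty_cohort <- function() {
  data.frame(birth_id = character(), location_id = character(),
             birth_date = as_date(character()), gestational_weeks = integer(),
             sex = character(), aboriginal = integer(),
             first_pregnancy = integer(), mother_age_band = character(),
             preterm = integer(), birthweight_g = numeric(),
             conception_date = as_date(character()),
             stringsAsFactors = FALSE)
}

#' Generate a synthetic birth cohort with known ground truth
#'
#' Samples conception dates, locations, sexes and covariates, computes each
#' pregnancy's exposure under the DGP's declared metric, draws the preterm
#' outcome from the latent probability, then draws gestational length
#' (uniform over the preterm or term week range) and the birth date
#' (`conception + 7 * weeks`). A birthweight-like continuous outcome is
#' generated from an analogous linear model and top/bottom-coded at the 2.5th
#' and 97.5th percentiles.
#'
#' @param weather daily weather covering every sampled gestation schedule
#'   (273 days from the latest possible conception date).
#' @param dgp a [cohort_dgp()] object.
#' @param seed integer seed.
#' @param locations optional character vector of location ids to sample from
#'   (default: all locations present in `weather`).
#' @return a list with `births` (the cohort table) and `truth` (a
#'   `truth_record`: the exact DGP coefficients, per-birth latent
#'   probabilities and the clipping rate).
#' @export
gen_cohort <- function(weather, dgp, seed, locations = NULL) {
  stopifnot(inherits(dgp, "cohort_dgp"))
  if (missing(seed) || is.null(seed)) stop("a seed must be supplied")
  locations <- locations %||% unique(weather$location_id)
  n <- dgp$n_births
  if (n == 0L) {
    truth <- new_truth_record(dgp, numeric(0), character(0), 0, seed)
    return(list(births = empty_cohort(), truth = truth))
  }
  wrange <- range(as_date(weather$date))
  need_end <- dgp$conception_range[2] + 273L
  if (wrange[1] > dgp$conception_range[1] || wrange[2] < need_end - 1L) {
    stop("weather must cover every gestation window: need [",
         dgp$conception_range[1], ", ", need_end, "), have [",
         wrange[1], ", ", wrange[2], "]")
  }

  set.seed(seed)
  span <- as.integer(dgp$conception_range[2] - dgp$conception_range[1])
  conception <- dgp$conception_range[1] +
    sample.int(span + 1L, n, replace = TRUE) - 1L
  births <- data.frame(
    birth_id = sprintf("B%06d", seq_len(n)),
    location_id = sample(locations, n, replace = TRUE),
    conception_date = conception,
    sex = sample(c("M", "F"), n, replace = TRUE, prob = c(0.512, 0.488)),
    aboriginal = rbinom(n, 1L, 0.33),
    first_pregnancy = rbinom(n, 1L, 0.35),
    mother_age_band = sample(age_band_levels(), n, replace = TRUE,
                             prob = c(0.08, 0.22, 0.30, 0.22, 0.13, 0.05)),
    stringsAsFactors = FALSE
  )
  ex <- build_exposures(births, weather, dgp$metric)

  p <- rep(dgp$baseline_preterm_rate, n)
  eta <- numeric(n)
  if (length(dgp$band_effects)) {
    Xh <- as.matrix(ex[, names(dgp$band_effects), drop = FALSE])
    if (isTRUE(dgp$center_exposures)) {
      cell <- paste(births$location_id, month_of(births$conception_date))
      for (j in seq_len(ncol(Xh))) {
        Xh[, j] <- Xh[, j] - ave(Xh[, j], cell)
      }
    }
    eta <- eta + drop(Xh %*% dgp$band_effects)
  }
  if (length(dgp$covariate_effects)) {
    C <- covariate_matrix(births)
    eta <- eta + drop(C[, names(dgp$covariate_effects), drop = FALSE] %*%
                        dgp$covariate_effects)
  }
  if (dgp$link == "linear") {
    p_raw <- p + eta
    p <- clip01(p_raw)
    clip_frac <- mean(p_raw != p)
  } else {
    p <- plogis(qlogis(dgp$baseline_preterm_rate) + eta)
    clip_frac <- 0
  }

  births$preterm <- rbinom(n, 1L, p)
  weeks <- integer(n)
  pre <- births$preterm == 1L
  weeks[pre] <- sample(dgp$gestation_preterm, sum(pre), replace = TRUE)
  weeks[!pre] <- sample(dgp$gestation_term, sum(!pre), replace = TRUE)
  births$gestational_weeks <- weeks
  births$birth_date <- births$conception_date + 7L * weeks

  bw <- dgp$birthweight
  bweight <- rnorm(n, bw$mean, bw$sd) + bw$preterm_shift * births$preterm
  if (length(bw$effects)) {
    bad <- setdiff(names(bw$effects), names(ex))
    if (length(bad)) stop("birthweight effect name(s) not in exposure table: ",
                          paste(bad, collapse = ", "))
    bweight <- bweight + drop(as.matrix(ex[, names(bw$effects), drop = FALSE]) %*%
                                bw$effects)
  }
  lo <- quantile(bweight, 0.025)
  hi <- quantile(bweight, 0.975)
  births$birthweight_g <- pmin(pmax(bweight, lo), hi)

  births <- births[, c("birth_id", "location_id", "birth_date",
                       "gestational_weeks", "sex", "aboriginal",
                       "first_pregnancy", "mother_age_band", "preterm",
                       "birthweight_g", "conception_date")]
  truth <- new_truth_record(dgp, p, births$birth_id, clip_frac, seed)
  list(births = births, truth = truth)
}

covariate_matrix <- function(births) {
  ab <- factor(as.character(births$mother_age_band), levels = age_band_levels())
  A <- sapply(setdiff(age_band_levels(), "25_29"), function(l) as.numeric(ab == l))
  colnames(A) <- paste0("age_", setdiff(age_band_levels(), "25_29"))
  cbind(first_pregnancy = as.numeric(births$first_pregnancy),
        aboriginal = as.numeric(births$aboriginal), A)
}

new_truth_record <- function(dgp, latent_prob, birth_id, clip_frac, seed) {
  structure(list(
    metric = dgp$metric$name,
    baseline_preterm_rate = dgp$baseline_preterm_rate,
    band_effects = as.list(dgp$band_effects %||% setNames(numeric(0), character(0))),
    covariate_effects = as.list(dgp$covariate_effects %||% setNames(numeric(0), character(0))),
    link = dgp$link,
    clip_fraction = clip_frac,
    seed = seed,
    birth_id = birth_id,
    latent_prob = latent_prob
  ), class = "truth_record")
}

#' Write / read a simulation truth record
#'
#' The truth record (DGP coefficients and per-birth latent probabilities)
#' round-trips losslessly through structured JSON text.
#'
#' @param truth a `truth_record` from [gen_cohort()].
#' @param path file path.
#' @return `read_truth()` returns the `truth_record`.
#' @export
write_truth <- function(truth, path) {
  stopifnot(inherits(truth, "truth_record"))
  jsonlite::write_json(unclass(truth), path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$band_effects <- as.list(x$band_effects)
  x$covariate_effects <- as.list(x$covariate_effects)
  x$birth_id <- as.character(x$birth_id %||% character(0))
  x$latent_prob <- as.numeric(x$latent_prob %||% numeric(0))
  structure(x, class = "truth_record")
}

#' Apply the analysis-sample exclusion filters
#'
#' Removes records whose location could not be geocoded (missing or empty
#' `location_id`) and, among the remainder, records missing any model
#' covariate (`sex`, `aboriginal`, `first_pregnancy`, `mother_age_band`,
#' `gestational_weeks`). Row order is preserved and per-reason counts are
#' reported.
#'
#' @param births a birth-record data frame.
#' @param covariates covariate columns whose missingness excludes a record.
#' @return a list with `births` (the filtered table) and `report` (named
#'   integer vector: `total`, `ungeocodable`, `missing_covariates`,
#'   `retained`).
#' @export
apply_exclusions <- function(births,
                             covariates = c("sex", "aboriginal",
                                            "first_pregnancy",
                                            "mother_age_band",
                                            "gestational_weeks")) {
  if (nrow(births) == 0L) {
    return(list(births = births,
                report = c(total = 0L, ungeocodable = 0L,
                           missing_covariates = 0L, retained = 0L)))
  }
  assert_columns(births, "location_id", "births")
  loc <- births$location_id
  no_loc <- is.na(loc) | (is.character(loc) & !is.na(loc) & loc == "")
  present <- intersect(covariates, names(births))
  miss_cov <- !no_loc & !complete.cases(births[, present, drop = FALSE])
  keep <- !no_loc & !miss_cov
  list(
    births = births[keep, , drop = FALSE],
    report = c(total = nrow(births),
               ungeocodable = sum(no_loc),
               missing_covariates = sum(miss_cov),
               retained = sum(keep))
  )
}
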