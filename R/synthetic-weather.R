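#' Climate zone parameters for the synthetic weather generator
#'
#' Parameter sets describing an annual temperature and humidity cycle for one
#' climate zone. The two built-in zones emulate the Northern Territory:
#' a hot, humid tropical zone (Darwin-like: wet-season days roughly 25-33 C,
#' dry-season days roughly 20-30 C, weak coupling between daily maximum and
#' minimum, humidity negatively correlated with temperature) and an arid zone
#' (Alice-Springs-like: summer days roughly 20-35 C, winter days roughly
#' 4-20 C, strong max/min coupling).
#'
#' The generative model is: daily maximum = annual cosine + AR(1) Gaussian
#' noise; diurnal range = its own seasonal cosine + independent noise (large
#' range noise produces the low tropical max/min correlation, small range
#' noise the high arid one); minimum = maximum - range; relative humidity =
#' seasonal cosine (its peak may lag the temperature peak) + a coupling term
#' proportional to the daily maximum's deviation from the annual mean + noise,
#' clipped to \[0, 100\].
#'
#' @param zone `"tropical"` or `"arid"` (selects the default set).
#' @param ... named overrides of individual fields.
#' @return an object of class `climate_zone_params`.
#' @examples
#' climate_zone_params("tropical")
#' climate_zone_params("arid", noise_sd_max = 0)
#' @export
climate_zone_params <- function(zone = c("tropical", "arid"), ...) {
  zone <- match.arg(zone)
  defaults <- switch(zone,
    tropical = list(
      zone_label = "tropical",
      tmax_mean_annual = 31.2,
      tmax_seasonal_amplitude = 1.0,
      diurnal_range_mean = 5.6,
      diurnal_range_seasonal_amplitude = 1.8,
      diurnal_range_peak_day_of_year = 196, # widest range mid-dry-season
      noise_sd_max = 0.8,
      noise_sd_range = 1.0,
      ar1_coefficient = 0.6,
      rh_mean = 70,
      rh_seasonal_amplitude = 8,
      rh_temp_coupling = -2.5,
      rh_noise_sd = 4,
      peak_day_of_year = 335,   # build-up: hottest around early December
      rh_peak_day_of_year = 35  # humidity peaks in the wet season proper
    ),
    arid = list(
      zone_label = "arid",
      tmax_mean_annual = 27.5,
      tmax_seasonal_amplitude = 7.5,
      diurnal_range_mean = 15.5,
      diurnal_range_seasonal_amplitude = -0.5,
      diurnal_range_peak_day_of_year = 15,
      noise_sd_max = 2.5,
      noise_sd_range = 0.7,
      ar1_coefficient = 0.7,
      rh_mean = 35,
      rh_seasonal_amplitude = 10,
      rh_temp_coupling = -0.8,
      rh_noise_sd = 5,
      peak_day_of_year = 15,    # mid-summer (January)
      rh_peak_day_of_year = 196
    )
  )
  overrides <- list(...)
  unknown <- setdiff(names(overrides), names(defaults))
  if (length(unknown)) stop("unknown climate parameter(s): ", paste(unknown, collapse = ", "))
  params <- utils::modifyList(defaults, overrides)
  validate_climate_zone_params(params)
  structure(params, class = "climate_zone_params")
}

validate_climate_zone_params <- function(p) {
  num <- c(
    "tmax_mean_annual", "tmax_seasonal_amplitude", "diurnal_range_mean",
    "diurnal_range_seasonal_amplitude", "diurnal_range_peak_day_of_year",
    "noise_sd_max", "noise_sd_range", "ar1_coefficient", "rh_mean",
    "rh_seasonal_amplitude", "rh_temp_coupling", "rh_noise_sd",
    "peak_day_of_year", "rh_peak_day_of_year"
  )
  for (f in num) {
    if (!is.numeric(p[[f]]) || length(p[[f]]) != 1L || !is.finite(p[[f]])) {
      stop("climate parameter ", f, " must be a finite number")
    }
  }
  if (p$noise_sd_max < 0 || p$noise_sd_range < 0 || p$rh_noise_sd < 0) {
    stop("noise standard deviations must be non-negative")
  }
  if (p$ar1_coefficient < 0 || p$ar1_coefficient >= 1) {
    stop("ar1_coefficient must lie in [0, 1)")
  }
  if (p$diurnal_range_mean <= 0) stop("diurnal_range_mean must be positive")
  if (p$rh_mean < 0 || p$rh_mean > 100) stop("rh_mean must lie in [0, 100]")
  invisible(p)
}

seasonal_phase <- function(doy, peak_day) cos(2 * pi * (doy - peak_day) / 365.25)

day_of_year <- function(d) as.integer(format(as_date(d), "%j"))

ar1_noise <- function(n, sd, phi) {
  if (sd == 0 || n == 0L) return(numeric(n))
  innov <- rnorm(n, 0, sd * sqrt(1 - phi^2))
  innov[1] <- rnorm(1, 0, sd) # stationary start
  as.numeric(stats::filter(innov, phi, method = "recursive"))
}

#' Generate daily weather for a set of locations
#'
#' Simulates gap-free daily maximum temperature, minimum temperature and
#' relative humidity for each location under one climate-zone parameter set.
#' All locations share the zone's seasonal curves but draw independent noise.
#'
#' @param params a [climate_zone_params()] object.
#' @param locations a character vector of location ids, or a data frame with a
#'   `location_id` column.
#' @param dates a `Date` vector; a length-2 vector is treated as an inclusive
#'   interval and expanded to a daily sequence.
#' @param seed integer seed; identical `(params, locations, dates, seed)`
#'   reproduce identical output.
#' @return a data frame with columns `location_id`, `date`, `tmax_c`,
#'   `tmin_c`, `rh_pct`; every day satisfies `tmin_c <= tmax_c` and
#'   `rh_pct` in \[0, 100\].
#' @examples
#' w <- gen_weather(climate_zone_params("tropical"), "T1",
#'                  as.Date(c("2004-01-01", "2004-03-01")), seed = 1)
#' head(w)
#' @export
gen_weather <- function(params, locations, dates, seed) {
  stopifnot(inherits(params, "climate_zone_params"))
  if (is.data.frame(locations)) {
    assert_columns(locations, "location_id", "locations")
    locations <- locations$location_id
  }
  locations <- as.character(locations)
  if (length(locations) == 0L) stop("empty location list")
  if (anyDuplicated(locations)) stop("duplicate location ids")
  if (missing(seed) || is.null(seed)) stop("a seed must be supplied")
  dates <- expand_dates(dates)
  n <- length(dates)
  doy <- day_of_year(dates)

  set.seed(seed)
  seas_tmax <- params$tmax_mean_annual +
    params$tmax_seasonal_amplitude * seasonal_phase(doy, params$peak_day_of_year)
  seas_range <- params$diurnal_range_mean +
    params$diurnal_range_seasonal_amplitude *
      seasonal_phase(doy, params$diurnal_range_peak_day_of_year)
  seas_rh <- params$rh_mean +
    params$rh_seasonal_amplitude * seasonal_phase(doy, params$rh_peak_day_of_year)

  out <- vector("list", length(locations))
  for (i in seq_along(locations)) {
    tmax <- seas_tmax + ar1_noise(n, params$noise_sd_max, params$ar1_coefficient)
    rng <- pmax(seas_range + rnorm(n, 0, params$noise_sd_range), 0)
    tmin <- tmax - rng
    rh <- seas_rh +
      params$rh_temp_coupling * (tmax - params$tmax_mean_annual) +
      rnorm(n, 0, params$rh_noise_sd)
    out[[i]] <- data.frame(
      location_id = locations[i],
      date = dates,
      tmax_c = tmax,
      tmin_c = tmin,
      rh_pct = pmin(pmax(rh, 0), 100),
      stringsAsFactors = FALSE
    )
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Sample Northern-Territory-like location coordinates
#'
#' Draws locations inside a tropical (north) and an arid (central/south)
#' latitude-longitude box. Points are spread widely, so most locations end up
#' in their own 50-mile cluster while a few close pairs exercise merging.
#'
#' @param n_tropical,n_arid number of locations per zone.
#' @param seed integer seed.
#' @return a data frame `location_id`, `lat`, `lon`, `zone`.
#' @export
nt_locations <- function(n_tropical = 5, n_arid = 5, seed = 1) {
  set.seed(seed)
  make <- function(n, prefix, lat_range, lon_range, zone) {
    if (n == 0L) return(NULL)
    data.frame(
      location_id = sprintf("%s%02d", prefix, seq_len(n)),
      lat = runif(n, lat_range[1], lat_range[2]),
      lon = runif(n, lon_range[1], lon_range[2]),
      zone = zone,
      stringsAsFactors = FALSE
    )
  }
  rbind(
    make(n_tropical, "T", c(-16.5, -11.2), c(129.0, 137.5), "tropical"),
    make(n_arid, "A", c(-26.0, -17.5), c(129.5, 137.5), "arid")
  )
}
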