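#' Temperature band schemes
#'
#' A band scheme partitions the real temperature line into ordered half-open
#' intervals `[lower, upper)`. Printed labels like "20-24.99" correspond to
#' the interval `[20, 25)`, so a temperature of exactly 25.0 falls in the
#' 25-29.99 band. One band is designated the omitted (reference) category for
#' regression designs.
#'
#' @param breaks strictly increasing finite interior breakpoints, degrees C.
#' @param labels band labels, one more than `breaks`.
#' @param omitted the label of the omitted (reference) band.
#' @return an object of class `band_scheme`.
#' @examples
#' band_scheme(c(20, 25, 30, 35, 40),
#'             c("lt20", "20_25", "25_30", "30_35", "35_40", "ge40"),
#'             omitted = "25_30")
#' @export
band_scheme <- function(breaks, labels, omitted) {
  if (any(!is.finite(breaks)) || is.unsorted(breaks, strictly = TRUE)) {
    stop("breaks must be strictly increasing finite numbers")
  }
  if (length(labels) != length(breaks) + 1L) {
    stop("need exactly length(breaks) + 1 labels")
  }
  if (anyDuplicated(labels)) stop("band labels must be unique")
  if (!omitted %in% labels) stop("omitted label must be one of the band labels")
  structure(list(breaks = breaks, labels = labels, omitted = omitted),
            class = "band_scheme")
}

# index of the band containing each value under the half-open convention
band_index <- function(x, scheme) {
  findInterval(x, scheme$breaks, left.open = FALSE) + 1L
}

# Built-in schemes: daily max and min air temperature, average and max wet bulb.
scheme_tmax <- function() {
  band_scheme(c(20, 25, 30, 35, 40),
              c("lt20", "20_25", "25_30", "30_35", "35_40", "ge40"),
              omitted = "25_30")
}
scheme_tmin <- function() {
  band_scheme(c(5, 10, 15, 20, 25),
              c("lt5", "5_10", "10_15", "15_20", "20_25", "ge25"),
              omitted = "15_20")
}
scheme_wb_avg <- function() {
  band_scheme(c(10, 15, 20, 25),
              c("lt10", "10_15", "15_20", "20_25", "ge25"),
              omitted = "15_20")
}
scheme_wb_max <- function() {
  band_scheme(c(10, 15, 20, 25, 30),
              c("lt10", "10_15", "15_20", "20_25", "25_30", "ge30"),
              omitted = "20_25")
}

#' Built-in heat exposure metrics
#'
#' Returns the specification of one of the five heat metrics:
#' \describe{
#'   \item{benchmark}{day counts of daily maximum temperature in 5-degree
#'     bands (under 20 through 40+), omitted band 25-29.99.}
#'   \item{trimester_average}{the trimester mean of daily maximum temperature.}
#'   \item{heatwave_count}{the number of Excess-Heat-Factor heatwaves starting
#'     in each trimester.}
#'   \item{max_and_min}{the benchmark bands plus day counts of daily minimum
#'     temperature in 5-degree bands (under 5 through 25+), omitted band
#'     15-19.99.}
#'   \item{wet_bulb}{day counts of daily average wet-bulb temperature
#'     (bands under 10 through 25+, omitted 15-19.99) plus daily maximum
#'     wet-bulb temperature (bands under 10 through 30+, omitted 20-24.99).}
#' }
#'
#' @param name metric name.
#' @return an object of class `heat_metric` with elements `name` and `terms`;
#'   each term describes the underlying daily field, the summary type
#'   (`"bands"`, `"mean"` or `"hw_count"`), the regressor-name prefix, and the
#'   band scheme where applicable.
#' @seealso [metric_regressors()], [build_exposures()]
#' @export
heat_metric <- function(name = c("benchmark", "trimester_average",
                                 "heatwave_count", "max_and_min", "wet_bulb")) {
  name <- match.arg(name)
  terms <- switch(name,
    benchmark = list(
      list(field = "tmax_c", type = "bands", prefix = "max", scheme = scheme_tmax())
    ),
    trimester_average = list(
      list(field = "tmax_c", type = "mean", prefix = "avg_tmax")
    ),
    heatwave_count = list(
      list(field = "ehf", type = "hw_count", prefix = "hw_count")
    ),
    max_and_min = list(
      list(field = "tmax_c", type = "bands", prefix = "max", scheme = scheme_tmax()),
      list(field = "tmin_c", type = "bands", prefix = "min", scheme = scheme_tmin())
    ),
    wet_bulb = list(
      list(field = "wb_mean_c", type = "bands", prefix = "wbavg", scheme = scheme_wb_avg()),
      list(field = "wb_max_c", type = "bands", prefix = "wbmax", scheme = scheme_wb_max())
    )
  )
  structure(list(name = name, terms = terms), class = "heat_metric")
}

as_heat_metric <- function(metric) {
  if (inherits(metric, "heat_metric")) return(metric)
  heat_metric(metric)
}

term_colnames <- function(term, k) {
  if (term$type == "bands") {
    paste0(term$prefix, "_", term$scheme$labels, "_t", k)
  } else {
    paste0(term$prefix, "_t", k)
  }
}

#' Regressor names of a heat metric
#'
#' @param metric a [heat_metric()] object or metric name.
#' @param include_omitted also list the omitted-band columns (default `FALSE`).
#' @return character vector of regressor (column) names, trimester-indexed.
#' @export
metric_regressors <- function(metric, include_omitted = FALSE) {
  metric <- as_heat_metric(metric)
  cols <- unlist(lapply(metric$terms, function(tm) {
    unlist(lapply(1:3, function(k) term_colnames(tm, k)))
  }))
  if (!include_omitted) cols <- setdiff(cols, metric_omitted(metric))
  cols
}

#' Omitted-band regressor names of a heat metric
#'
#' @param metric a [heat_metric()] object or metric name.
#' @return character vector of the omitted reference columns (may be empty).
#' @export
metric_omitted <- function(metric) {
  metric <- as_heat_metric(metric)
  unlist(lapply(metric$terms, function(tm) {
    if (tm$type != "bands") return(character())
    paste0(tm$prefix, "_", tm$scheme$omitted, "_t", 1:3)
  }))
}
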