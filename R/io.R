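#' Read and write the package's CSV file contracts
#'
#' Tabular artifacts use fixed CSV dialects: weather
#' (`location_id,date,tmax_c,tmin_c,rh_pct` plus optional derived columns
#' `tmean_c,wb_mean_c,wb_max_c,ehf`), births
#' (`birth_id,location_id,birth_date,gestational_weeks,sex,aboriginal,first_pregnancy,mother_age_band,preterm,birthweight_g`),
#' locations (`location_id,lat,lon`), cluster assignments
#' (`location_id,cluster_id`), heatwave events
#' (`location_id,start_date,end_date,duration`) and exposure tables
#' (`birth_id` plus one column per regressor). Dates are ISO-8601,
#' temperatures degrees C, day intervals half-open.
#'
#' @param x the table to write.
#' @param path file path.
#' @return the readers return validated data frames.
#' @name heatbands_io
NULL

#' @rdname heatbands_io
#' @export
write_weather_csv <- function(x, path) {
  assert_columns(x, c("location_id", "date", "tmax_c", "tmin_c", "rh_pct"), "weather")
  write.csv(x, path, row.names = FALSE)
  invisible(path)
}

#' @rdname heatbands_io
#' @export
read_weather_csv <- function(path) {
  x <- read.csv(path, stringsAsFactors = FALSE)
  assert_columns(x, c("location_id", "date", "tmax_c", "tmin_c", "rh_pct"), path)
  x$date <- as_date(x$date)
  x$location_id <- as.character(x$location_id)
  if (any(x$tmin_c > x$tmax_c)) stop("invalid weather file: tmin_c > tmax_c")
  if (any(x$rh_pct < 0 | x$rh_pct > 100)) stop("invalid weather file: rh_pct outside [0, 100]")
  x
}

#' @rdname heatbands_io
#' @export
write_births_csv <- function(x, path) {
  cols <- c("birth_id", "location_id", "birth_date", "gestational_weeks",
            "sex", "aboriginal", "first_pregnancy", "mother_age_band",
            "preterm", "birthweight_g")
  assert_columns(x, cols, "births")
  write.csv(x[, cols], path, row.names = FALSE)
  invisible(path)
}

#' @rdname heatbands_io
#' @export
read_births_csv <- function(path) {
  x <- read.csv(path, stringsAsFactors = FALSE)
  assert_columns(x, c("birth_id", "location_id", "birth_date",
                      "gestational_weeks", "sex"), path)
  x$birth_date <- as_date(x$birth_date)
  x$birth_id <- as.character(x$birth_id)
  x$location_id <- as.character(x$location_id)
  x
}

#' @rdname heatbands_io
#' @export
write_exposures_csv <- function(x, path) {
  assert_columns(x, "birth_id", "exposures")
  write.csv(x, path, row.names = FALSE)
  invisible(path)
}

#' @rdname heatbands_io
#' @export
read_exposures_csv <- function(path) {
  x <- read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  assert_columns(x, "birth_id", path)
  x$birth_id <- as.character(x$birth_id)
  x
}
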