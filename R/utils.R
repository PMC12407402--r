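`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a stage-specific random seed from a pipeline seed
#'
#' Each pipeline stage draws from its own substream so that changing one
#' stage's draws never perturbs another's. Stage labels are fixed; the derived
#' seed stays inside the 32-bit integer range.
#'
#' @param seed integer master seed.
#' @param stage one of `"locations"`, `"weather"`, `"cohort"`, `"scenario"`.
#' @return an integer seed.
#' @export
stage_seed <- function(seed, stage) {
  offsets <- c(locations = 1, weather = 2, cohort = 3, scenario = 4)
  if (!stage %in% names(offsets)) {
    stop("unknown stage label: ", stage)
  }
  as.integer((as.numeric(seed) + 97003 * offsets[[stage]]) %% 2147483647)
}

assert_columns <- function(df, cols, what = deparse(substitute(df))) {
  missing <- setdiff(cols, names(df))
  if (length(missing)) {
    stop(what, " is missing required column(s): ", paste(missing, collapse = ", "))
  }
  invisible(df)
}

as_date <- function(x) {
  if (inherits(x, "Date")) return(x)
  as.Date(x)
}

# inclusive daily sequence; a length-2 input is treated as an interval
expand_dates <- function(dates) {
  dates <- as_date(dates)
  if (anyNA(dates)) stop("dates contain NA")
  if (length(dates) == 2L && dates[1] <= dates[2]) {
    return(seq(dates[1], dates[2], by = "day"))
  }
  if (length(dates) < 1L) stop("empty date interval")
  dates
}

month_of <- function(d) as.integer(format(d, "%m"))
year_of <- function(d) as.integer(format(d, "%Y"))

check_gap_free <- function(dates, where = "weather series") {
  dates <- as_date(dates)
  if (length(dates) > 1L && any(diff(as.integer(dates)) != 1L)) {
    stop(where, " has gaps or unordered dates")
  }
  invisible(TRUE)
}

clip01 <- function(p) pmin(pmax(p, 0), 1)
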