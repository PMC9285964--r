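#' Extended day-of-year axis
#'
#' Phenology forecasting spans the year boundary: forcing accumulation for a
#' spring event can start in the preceding November. All model arithmetic
#' therefore uses an *extended day index* anchored to a reference (event)
#' year: day 1 is 1 January of the reference year, day 0 is 31 December of
#' the prior year, and 1 November of the prior year is day -60. Days after
#' 31 December of the reference year simply continue past 365/366.
#'
#' @param day Integer extended day index (vectorised).
#' @param date A `Date` vector.
#' @param ref_year The reference (event) year anchoring day 1.
#'
#' @return `day_to_date()` returns a `Date`; `date_to_day()` an integer
#'   vector; `day_month()` the calendar month (1-12) of each index.
#'
#' @examples
#' date_to_day(as.Date("2018-11-01"), ref_year = 2019) # -60
#' day_to_date(1, ref_year = 2019)                     # 2019-01-01
#' @name day-axis
NULL

#' @rdname day-axis
#' @export
day_to_date <- function(day, ref_year) {
  as.Date(paste0(ref_year, "-01-01")) + (as.integer(day) - 1L)
}

#' @rdname day-axis
#' @export
date_to_day <- function(date, ref_year) {
  as.integer(as.Date(date) - as.Date(paste0(ref_year, "-01-01"))) + 1L
}

#' @rdname day-axis
#' @export
day_month <- function(day, ref_year) {
  as.integer(format(day_to_date(day, ref_year), "%m"))
}
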