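# days per month on the 366-day (leap) calendar the JD convention uses
.month_days_leap <- c(31, 29, 31, 30, 31, 30, 31, 31, 30, 31, 30, 31)

#' Convert a reproduction-peak month to an approximate Julian day
#'
#' Monthly phenology reports are converted to day-of-year by assigning the
#' 15th day of the month (+/- 15 d precision) on a 366-day calendar. Under
#' the `"autumn-negative"` policy, months October-December map to negative
#' values (day-of-year minus 366), so the southern-edge autumn peaks line up
#' below the winter/spring peaks and the latitude-phenology relation stays
#' monotone instead of wrapping at New Year.
#'
#' @param month Integer month(s) in 1..12.
#' @param wrap_policy `"autumn-negative"` (default) or `"none"`.
#' @return Approximate Julian day (integer; negative for autumn months under
#'   the wrap policy). July gives 197, August 228, February 46 and November
#'   -46.
#' @export
#' @examples
#' month_to_julian_day(c(2, 7, 8, 11))  # 46 197 228 -46
#' month_to_julian_day(11, wrap_policy = "none")  # 320
month_to_julian_day <- function(month, wrap_policy = c("autumn-negative", "none")) {
  wrap_policy <- match.arg(wrap_policy)
  if (any(is.na(month)) || any(month != round(month)) ||
      any(month < 1) || any(month > 12)) {
    stop("month must be an integer in 1..12", call. = FALSE)
  }
  month <- as.integer(month)
  doy <- cumsum(c(0L, .month_days_leap[-12]))[month] + 15L
  if (wrap_policy == "autumn-negative") {
    doy <- ifelse(month >= 10L, doy - 366L, doy)
  }
  as.integer(doy)
}

#' Build a normalized phenology record
#'
#' A region's reproduction-peak timing is specified either as a month (then
#' converted via [month_to_julian_day()]) or as an explicit Julian day that
#' passes through unchanged; exactly one of the two must be supplied.
#'
#' @param region_id Identifier.
#' @param latitude Degrees North.
#' @param sst_mean Optional long-term mean SST, degrees C.
#' @param peak_month Optional month 1..12.
#' @param peak_jd Optional explicit approximate Julian day in \[-122, 366\].
#' @param wrap_policy Passed to [month_to_julian_day()].
#' @return An `asco_phenology_record`: list with `region_id`, `latitude`,
#'   `sst_mean`, `peak_month`, `peak_jd`.
#' @export
#' @examples
#' build_phenology_record("portugal", 42, peak_month = 11)$peak_jd  # -46
build_phenology_record <- function(region_id, latitude, sst_mean = NA_real_,
                                   peak_month = NULL, peak_jd = NULL,
                                   wrap_policy = c("autumn-negative", "none")) {
  wrap_policy <- match.arg(wrap_policy)
  has_month <- !is.null(peak_month) && !is.na(peak_month)
  has_jd <- !is.null(peak_jd) && !is.na(peak_jd)
  if (has_month == has_jd) {
    stop("supply exactly one of peak_month or peak_jd", call. = FALSE)
  }
  if (has_month) {
    peak_jd <- month_to_julian_day(peak_month, wrap_policy)
  } else {
    if (peak_jd < -122 || peak_jd > 366) {
      stop("peak_jd must lie in [-122, 366]", call. = FALSE)
    }
    peak_month <- NA_integer_
  }
  structure(
    list(region_id = as.character(region_id),
         latitude = as.numeric(latitude),
         sst_mean = as.numeric(sst_mean),
         peak_month = as.integer(peak_month),
         peak_jd = as.integer(peak_jd)),
    class = "asco_phenology_record")
}

#' @export
print.asco_phenology_record <- function(x, ...) {
  cat(sprintf("<asco_phenology_record> %s  lat %.2f N  peak JD %d (+/-15)\n",
              x$region_id, x$latitude, x$peak_jd))
  invisible(x)
}
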