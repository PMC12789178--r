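#' Convert calendar dates to April days
#'
#' The field convention for breeding phenology dates: 1 April is day 1, 31
#' March is day 0, and days count negatively into March. The year is taken
#' from the date itself.
#'
#' @param date a `Date` vector.
#' @return integer vector of April days.
#' @examples
#' april_day(as.Date("2021-04-01")) # 1
#' april_day(as.Date("2021-04-30")) # 30
#' @export
april_day <- function(date) {
  stopifnot(inherits(date, "Date"))
  yr <- as.integer(format(date, "%Y"))
  as.integer(date - as.Date(paste0(yr, "-03-31")))
}

#' Convert April days back to calendar dates
#'
#' @param day integer April day (1 April = 1).
#' @param year calendar year.
#' @return `Date` vector.
#' @export
april_date <- function(day, year) {
  as.Date(paste0(year, "-03-31")) + day
}

# decimal hours since local midnight for a POSIXct vector
hours_since_midnight <- function(ts) {
  lt <- as.POSIXlt(ts)
  lt$hour + lt$min / 60 + lt$sec / 3600
}

# TRUE for samples inside the night window [night_start, 24) U [0, night_end)
in_night_window <- function(hours, night_start = 21, night_end = 5) {
  hours >= night_start | hours < night_end
}

# deterministic sub-seed for an independent stream derived from a master seed
sub_seed <- function(seed, stream) {
  (as.integer(seed) %% 1000003L) * 1009L + 7919L * as.integer(stream)
}

# validate a scalar field, erroring with the field name
check_scalar <- function(x, name, lower = -Inf, allow_zero = TRUE) {
  if (length(x) != 1 || !is.numeric(x) || is.na(x)) {
    abort(sprintf("config field `%s` must be a single finite number", name))
  }
  ok <- if (allow_zero) x >= lower else x > lower
  if (!ok) {
    abort(sprintf(
      "config field `%s` must be %s %s (got %s)",
      name, if (allow_zero) ">=" else ">", format(lower), format(x)
    ))
  }
  invisible(x)
}

# quantise temperatures to the logger accuracy step
quantise_temp <- function(x, accuracy) {
  round(x / accuracy) * accuracy
}
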