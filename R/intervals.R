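#' Half-open calendar interval
#'
#' The atom of all person-time arithmetic in wyloss. An interval covers the
#' dates `[start, end)`: the start day is counted, the end day is not. This
#' convention makes lengths additive and guarantees that abutting spells
#' (one ending the day another begins) never double-count a day.
#'
#' `cal_interval()` is vectorised: `start` and `end` are recycled to a common
#' length and the result holds that many intervals.
#'
#' @param start,end Dates (or strings coercible via [as.Date()]). Must satisfy
#'   `start <= end` element-wise; an interval with `start == end` is empty.
#' @return An object of class `cal_interval`: a list with `Date` vectors
#'   `start` and `end`.
#' @examples
#' cal_interval("2012-04-01", "2018-03-31")
#' interval_days(cal_interval("2013-01-01", "2013-03-02")) # 60
#' @export
cal_interval <- function(start, end) {
  start <- as.Date(start)
  end <- as.Date(end)
  n <- max(length(start), length(end))
  if (n > 0L) {
    start <- rep_len(start, n)
    end <- rep_len(end, n)
  }
  if (anyNA(start) || anyNA(end)) {
    stop("cal_interval: start/end contain missing or unparseable dates", call. = FALSE)
  }
  if (any(end < start)) {
    bad <- which(end < start)[1L]
    stop(sprintf(
      "cal_interval: end precedes start (%s < %s)",
      format(end[bad]), format(start[bad])
    ), call. = FALSE)
  }
  structure(list(start = start, end = end), class = "cal_interval")
}

#' @export
length.cal_interval <- function(x) length(x$start)

#' @export
format.cal_interval <- function(x, ...) {
  ifelse(x$start == x$end, "[empty)",
    sprintf("[%s, %s)", format(x$start), format(x$end))
  )
}

#' @export
print.cal_interval <- function(x, ...) {
  cat("<cal_interval[", length(x), "]>\n", sep = "")
  if (length(x)) print(format(x), quote = FALSE)
  invisible(x)
}

#' @export
`[.cal_interval` <- function(x, i) cal_interval(x$start[i], x$end[i])

#' Interval length in days and years
#'
#' Length of a half-open interval: `end - start` days. Years divide the day
#' count by 365.25, the calendar-stable convention used throughout the
#' package for converting lost days to lost working years.
#'
#' @param x A [cal_interval].
#' @return Numeric vector of day (or year) counts, zero for empty intervals.
#' @export
interval_days <- function(x) {
  stopifnot(inherits(x, "cal_interval"))
  as.numeric(x$end - x$start)
}

#' @rdname interval_days
#' @export
interval_years <- function(x) interval_days(x) / 365.25

#' @rdname interval_days
#' @export
interval_is_empty <- function(x) interval_days(x) == 0

#' Intersect two calendar intervals
#'
#' Returns the maximal interval contained in both arguments; disjoint inputs
#' yield an empty interval (never an error). Vectorised with recycling.
#'
#' @param a,b [cal_interval] objects.
#' @return A [cal_interval] of the common length.
#' @examples
#' w <- cal_interval("2012-04-01", "2018-03-31")
#' interval_intersect(cal_interval("2012-03-01", "2012-05-01"), w)
#' @export
interval_intersect <- function(a, b) {
  stopifnot(inherits(a, "cal_interval"), inherits(b, "cal_interval"))
  s <- pmax(a$start, b$start)
  e <- pmin(a$end, b$end)
  e <- pmax(s, e) # disjoint -> empty interval anchored at the later start
  cal_interval(s, e)
}

#' Observation window with working-age limits
#'
#' The study frame: a calendar window plus the working-age band. The defaults
#' follow the six fiscal years April 2012 through March 2018 and the 20-59
#' working-age convention (60 being the statutory retirement age), both
#' configurable.
#'
#' The calendar window is half-open, so the default runs through 2018-03-30
#' inclusive; `end` is the first day outside the study.
#'
#' @param start,end Window start (inclusive) and end (exclusive) dates.
#' @param min_age,max_age Working-age limits in whole years; a person
#'   contributes from their `min_age`-th birthday up to (excluding) their
#'   `max_age`-th birthday.
#' @return An object of class `obs_window`.
#' @export
obs_window <- function(start = "2012-04-01", end = "2018-03-31",
                       min_age = 20L, max_age = 60L) {
  window <- cal_interval(start, end)
  if (length(window) != 1L || interval_is_empty(window)) {
    stop("obs_window: window must be a single non-empty interval", call. = FALSE)
  }
  min_age <- as.integer(min_age)
  max_age <- as.integer(max_age)
  if (is.na(min_age) || is.na(max_age) || min_age >= max_age || min_age < 0L) {
    stop("obs_window: need 0 <= min_age < max_age", call. = FALSE)
  }
  structure(
    list(window = window, min_age = min_age, max_age = max_age),
    class = "obs_window"
  )
}

#' @export
print.obs_window <- function(x, ...) {
  cat(sprintf(
    "<obs_window> %s, working age %d-%d\n",
    format(x$window), x$min_age, x$max_age - 1L
  ))
  invisible(x)
}

#' Add whole years to a date, rolling back impossible days
#'
#' Birthday arithmetic: `add_years("1996-02-29", 20)` rolls back to
#' 2016-02-28 when the target year lacks a Feb 29 (here it does not, but
#' 21 years would). Thin wrapper over [lubridate::add_with_rollback()].
#'
#' @param date Date vector.
#' @param n Integer number of years.
#' @return Date vector.
#' @export
add_years <- function(date, n) {
  lubridate::add_with_rollback(as.Date(date), lubridate::years(n))
}

#' Personal observation window of an employee
#'
#' Intersects the study window with the employee's working-age span, i.e.
#' `[birth + min_age years, birth + max_age years)`. An employee younger than
#' `min_age` at the window start begins contributing on their `min_age`-th
#' birthday; one reaching `max_age` before the window end stops contributing
#' on that birthday. Employees outside working age for the whole window get
#' an empty interval.
#'
#' @param birth_date Date vector of birth dates.
#' @param window An [obs_window].
#' @return A [cal_interval], one element per birth date.
#' @examples
#' w <- obs_window()
#' personal_window(as.Date("1955-01-15"), w) # ends on the 60th birthday
#' personal_window(as.Date("1994-06-01"), w) # starts on the 20th birthday
#' @export
personal_window <- function(birth_date, window) {
  stopifnot(inherits(window, "obs_window"))
  birth_date <- as.Date(birth_date)
  working <- cal_interval(
    add_years(birth_date, window$min_age),
    add_years(birth_date, window$max_age)
  )
  interval_intersect(working, cal_interval(
    rep(window$window$start, length(birth_date)),
    rep(window$window$end, length(birth_date))
  ))
}
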