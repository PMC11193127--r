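## Small validation and date helpers (patterns live in aaa-constants.R).

is_atc <- function(x) grepl(ATC_PATTERN, x)
is_icpc2 <- function(x) grepl(ICPC2_PATTERN, x)
is_gtin <- function(x) grepl(GTIN_PATTERN, x)

#' Age in completed years
#'
#' Completed-years ("birthday") age: the age increments on the anniversary of
#' the birth date. A Feb-29 birthday increments on Mar 1 in non-leap years.
#'
#' @param birth,date `Date` vectors (recycled to common length).
#' @return Integer vector of completed years.
#' @examples
#' age_completed_years(as.Date("1956-03-01"), as.Date("2021-02-28")) # 64
#' age_completed_years(as.Date("1956-03-01"), as.Date("2021-03-01")) # 65
#' @export
age_completed_years <- function(birth, date) {
  birth <- as.Date(birth)
  date <- as.Date(date)
  n <- max(length(birth), length(date))
  birth <- rep_len(birth, n)
  date <- rep_len(date, n)
  by <- as.integer(format(birth, "%Y"))
  bm <- as.integer(format(birth, "%m"))
  bd <- as.integer(format(birth, "%d"))
  dy <- as.integer(format(date, "%Y"))
  dm <- as.integer(format(date, "%m"))
  dd <- as.integer(format(date, "%d"))
  dy - by - as.integer(dm < bm | (dm == bm & dd < bd))
}

#' Add whole years to a date
#'
#' `add_years(birth, a)` is the first calendar day on which
#' [age_completed_years()] equals `a` (Feb-29 anniversaries fall on Mar 1 in
#' non-leap years).
#'
#' @param date `Date` vector.
#' @param n integer number of years to add.
#' @return `Date` vector.
#' @export
add_years <- function(date, n) {
  date <- as.Date(date)
  y <- as.integer(format(date, "%Y")) + as.integer(n)
  md <- format(date, "%m-%d")
  # Feb 29 anniversary in a non-leap target year -> Mar 1
  leap <- (y %% 4 == 0 & y %% 100 != 0) | y %% 400 == 0
  md[md == "02-29" & !leap] <- "03-01"
  as.Date(paste0(y, "-", md))
}

# stop() with a class so tests can assert on error types
pim_stop <- function(msg, class, data = NULL) {
  cond <- structure(
    class = c(class, "pimscreen_error", "error", "condition"),
    list(message = msg, call = sys.call(-1), data = data)
  )
  stop(cond)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
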