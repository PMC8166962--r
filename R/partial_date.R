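#' Parse a partial date string
#'
#' Spontaneous-report databases record dates with varying completeness: a
#' full day (\code{"YYYYMMDD"}), a year-month (\code{"YYYYMM"}), or a bare
#' year (\code{"YYYY"}). Downstream time-to-onset analysis requires full
#' dates; partial dates are carried through the tables and excluded (with
#' accounting) at latency computation, never silently promoted.
#'
#' @param text character scalar; one of the three digit layouts.
#' @return an object of class \code{partial_date}: a list with fields
#'   \code{year}, \code{month} (or \code{NA}), \code{day} (or \code{NA})
#'   and \code{completeness} (\code{"full"}, \code{"year_month"} or
#'   \code{"year_only"}).
#' @examples
#' parse_partial_date("20200115")
#' parse_partial_date("202001")$completeness
#' @export
parse_partial_date <- function(text) {
  if (length(text) != 1L || is.na(text))
    stop("parse_partial_date() expects a single non-NA string", call. = FALSE)
  text <- as.character(text)
  if (!grepl("^[0-9]{4}([0-9]{2}([0-9]{2})?)?$", text))
    stop("not a recognised date layout (YYYYMMDD/YYYYMM/YYYY): ",
         sQuote(text), call. = FALSE)
  year <- as.integer(substr(text, 1L, 4L))
  month <- if (nchar(text) >= 6L) as.integer(substr(text, 5L, 6L)) else NA_integer_
  day <- if (nchar(text) == 8L) as.integer(substr(text, 7L, 8L)) else NA_integer_
  if (!is.na(month) && (month < 1L || month > 12L))
    stop("invalid month in date ", sQuote(text), call. = FALSE)
  if (!is.na(day)) {
    d <- as.Date(sprintf("%04d-%02d-%02d", year, month, day),
                 format = "%Y-%m-%d")
    if (is.na(d) || as.integer(format(d, "%d")) != day)
      stop("invalid calendar day in date ", sQuote(text), call. = FALSE)
  }
  completeness <- if (!is.na(day)) "full" else if (!is.na(month)) "year_month" else "year_only"
  structure(list(year = year, month = month, day = day,
                 completeness = completeness),
            class = "partial_date")
}

#' @export
format.partial_date <- function(x, ...) {
  switch(x$completeness,
         full = sprintf("%04d%02d%02d", x$year, x$month, x$day),
         year_month = sprintf("%04d%02d", x$year, x$month),
         year_only = sprintf("%04d", x$year))
}

#' @export
print.partial_date <- function(x, ...) {
  cat("<partial_date ", format(x), " (", x$completeness, ")>\n", sep = "")
  invisible(x)
}

#' Completeness of a vector of date strings
#'
#' Vectorised classifier over the stored digit-string representation.
#' Empty strings and \code{NA} classify as \code{NA}.
#'
#' @param x character vector of date strings.
#' @return character vector with values \code{"full"},
#'   \code{"year_month"}, \code{"year_only"} or \code{NA}.
#' @export
date_completeness <- function(x) {
  out <- rep(NA_character_, length(x))
  x <- as.character(x)
  ok <- !is.na(x) & grepl("^[0-9]{4}([0-9]{2}([0-9]{2})?)?$", x)
  out[ok & nchar(x) == 8L] <- "full"
  out[ok & nchar(x) == 6L] <- "year_month"
  out[ok & nchar(x) == 4L] <- "year_only"
  out
}

#' Ordinal day number of full date strings
#'
#' Converts \code{"YYYYMMDD"} strings to integer day counts (days since
#' 1970-01-01) so that latencies are plain differences. Anything less
#' complete than a full date maps to \code{NA}: latency arithmetic on
#' partial dates is meaningless and the exclusion is made explicit
#' upstream.
#'
#' @param x character vector of date strings.
#' @return integer vector; \code{NA} where the date is not full or invalid.
#' @export
date_ordinal <- function(x) {
  out <- rep(NA_integer_, length(x))
  full <- which(date_completeness(x) == "full")
  if (length(full)) {
    d <- as.Date(x[full], format = "%Y%m%d")
    out[full] <- as.integer(d)
  }
  out
}

# degrade a full date string to year_month (used by the simulator to
# emulate missing-day reporting)
degrade_to_year_month <- function(x) {
  ifelse(!is.na(x) & nchar(x) == 8L, substr(x, 1L, 6L), x)
}
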