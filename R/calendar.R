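#' ISO-8601 week calendar utilities
#'
#' The whole pipeline runs on an ISO-8601 weekly grid. A week is identified by
#' the pair (iso_year, iso_week); its canonical anchor date is its Thursday,
#' which is unique and always falls inside the ISO year (this is what makes
#' week arithmetic reducible to date arithmetic). A week is said to belong to
#' the calendar month that contains its Thursday.
#'
#' @name calendar
NULL

#' Thursday of an ISO week
#'
#' @param iso_year integer ISO year(s)
#' @param iso_week integer ISO week number(s), 1..52/53
#' @return `Date` vector of the Thursdays anchoring each week
#' @export
iso_week_thursday <- function(iso_year, iso_week) {
  stopifnot(length(iso_year) == length(iso_week) || length(iso_year) == 1L ||
              length(iso_week) == 1L)
  n_weeks <- weeks_in_iso_year(iso_year)
  bad <- iso_week < 1L | iso_week > n_weeks
  if (any(bad)) {
    stop(sprintf("invalid ISO week %d for year %d (year has %d weeks)",
                 iso_week[bad][1L], iso_year[bad][1L], n_weeks[bad][1L]))
  }
  # Jan 4 is always in ISO week 1; back up to that week's Monday.
  jan4 <- as.Date(sprintf("%d-01-04", iso_year))
  monday1 <- jan4 - (as.integer(format(jan4, "%u")) - 1L)
  monday1 + (iso_week - 1L) * 7L + 3L
}

#' Number of ISO weeks in a year (52 or 53)
#'
#' @param iso_year integer year(s)
#' @return integer vector
#' @export
weeks_in_iso_year <- function(iso_year) {
  # Dec 28 is always in the last ISO week of its year.
  as.integer(format(as.Date(sprintf("%d-12-28", iso_year)), "%V"))
}

#' ISO year/week of a date
#' @param date `Date` vector
#' @return data.frame with integer columns `iso_year`, `iso_week`
#' @export
date_to_iso_week <- function(date) {
  data.frame(iso_year = as.integer(format(date, "%G")),
             iso_week = as.integer(format(date, "%V")))
}

#' Successor of an ISO week
#'
#' Closed under year boundaries: week 52 (or 53 in long years) maps to week 1
#' of the next ISO year.
#' @param iso_year,iso_week integers
#' @param k number of weeks to advance (may be negative)
#' @return data.frame with columns `iso_year`, `iso_week`
#' @export
week_add <- function(iso_year, iso_week, k = 1L) {
  date_to_iso_week(iso_week_thursday(iso_year, iso_week) + 7L * k)
}

#' Sequence of consecutive ISO weeks
#' @param iso_year,iso_week start week
#' @param n length of the sequence
#' @return data.frame with columns `iso_year`, `iso_week`
#' @export
week_seq <- function(iso_year, iso_week, n) {
  stopifnot(n >= 1)
  date_to_iso_week(iso_week_thursday(iso_year, iso_week) + 7L * (seq_len(n) - 1L))
}

#' Number of weeks from one ISO week to another, inclusive of both
#' @param year1,week1 first week
#' @param year2,week2 last week
#' @return integer (negative if the second week precedes the first)
#' @export
weeks_between <- function(year1, week1, year2, week2) {
  as.integer(iso_week_thursday(year2, week2) - iso_week_thursday(year1, week1)) %/% 7L + 1L
}

#' Format ISO weeks as "YYYY-Www" labels
#' @param iso_year,iso_week integers
#' @return character vector like `"2016-W05"`
#' @export
week_label <- function(iso_year, iso_week) {
  sprintf("%04d-W%02d", as.integer(iso_year), as.integer(iso_week))
}

#' Parse "YYYY-Www" week labels
#' @param x character vector
#' @return data.frame with integer columns `iso_year`, `iso_week`; unparseable
#'   tokens raise an error naming the offending element
#' @export
parse_week <- function(x) {
  m <- regmatches(x, regexec("^([0-9]{4})-W([0-9]{2})$", x))
  bad <- vapply(m, length, 1L) != 3L
  if (any(bad)) {
    i <- which(bad)[1L]
    stop(sprintf("unparseable week token '%s' (element %d); expected YYYY-Www",
                 x[i], i))
  }
  data.frame(iso_year = as.integer(vapply(m, `[`, "", 2L)),
             iso_week = as.integer(vapply(m, `[`, "", 3L)))
}

#' Calendar month containing an ISO week
#'
#' A week belongs to the month containing its Thursday (ISO convention).
#' @param iso_year,iso_week integers
#' @return data.frame with columns `year`, `month`
#' @export
week_month <- function(iso_year, iso_week) {
  th <- iso_week_thursday(iso_year, iso_week)
  data.frame(year = as.integer(format(th, "%Y")),
             month = as.integer(format(th, "%m")))
}
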