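#' Read a weekly series from CSV
#'
#' Expects a comma-separated UTF-8 file with a header, a `week` column in
#' ISO-8601 week-date form (`YYYY-Www`, e.g. `2016-W05`) and one value column.
#' Rows may appear in any order; the result is sorted by week. Duplicated weeks
#' and coverage gaps are hard errors (surveillance series must be gap-free).
#'
#' @param path CSV file path
#' @param value_column name of the value column (default `"value"`)
#' @return a [weekly_series()]
#' @export
read_series_csv <- function(path, value_column = "value") {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!"week" %in% names(df)) stop(sprintf("%s: no 'week' column", path))
  if (!value_column %in% names(df)) {
    stop(sprintf("%s: no '%s' column", path, value_column))
  }
  wk <- tryCatch(parse_week(df$week), error = function(e) {
    # re-raise with the 1-based data row number for easier fixing
    m <- regmatches(conditionMessage(e),
                    regexec("element ([0-9]+)", conditionMessage(e)))[[1L]]
    row <- if (length(m) == 2L) as.integer(m[2L]) else NA_integer_
    stop(sprintf("%s row %s: %s", path, row, conditionMessage(e)))
  })
  th <- iso_week_thursday(wk$iso_year, wk$iso_week)
  if (anyDuplicated(th)) {
    d <- which(duplicated(th))[1L]
    stop(sprintf("%s: duplicate week %s",
                 path, week_label(wk$iso_year[d], wk$iso_week[d])))
  }
  ord <- order(th)
  weekly_series(wk$iso_year[ord], wk$iso_week[ord],
                as.numeric(df[[value_column]])[ord])
}

#' Write a weekly series to CSV
#'
#' Values are serialized with 17 significant digits so that
#' `read_series_csv(write_series_csv(s))` is an exact round trip.
#'
#' @param series a [weekly_series()]
#' @param path destination file path
#' @return `path`, invisibly
#' @export
write_series_csv <- function(series, path) {
  stopifnot(inherits(series, "weekly_series"))
  lines <- c("week,value",
             sprintf("%s,%s", week_label(series$iso_year, series$iso_week),
                     sprintf("%.17g", series$value)))
  writeLines(lines, path)
  invisible(path)
}

#' Align a monthly table onto the weekly grid
#'
#' Every ISO week is assigned to the month containing its Thursday. Under
#' `repeat` each week receives its month's value verbatim (a step function);
#' under `linear` weekly values are interpolated between month midpoints
#' (edges clamped to the nearest midpoint value).
#'
#' @param monthly data.frame with columns `year`, `month`, `value`; months must
#'   be contiguous
#' @param method `"repeat"` or `"linear"`
#' @return a [weekly_series()] covering every week whose Thursday falls inside
#'   the monthly table's span
#' @export
align_monthly_to_weekly <- function(monthly, method = c("repeat", "linear")) {
  method <- match.arg(method)
  stopifnot(all(c("year", "month", "value") %in% names(monthly)),
            nrow(monthly) >= 1L)
  monthly <- monthly[order(monthly$year, monthly$month), , drop = FALSE]
  m_start <- as.Date(sprintf("%d-%02d-01", monthly$year, monthly$month))
  if (nrow(monthly) > 1L) {
    expected <- seq(m_start[1L], by = "1 month", length.out = nrow(monthly))
    if (!identical(as.integer(m_start), as.integer(expected))) {
      miss_i <- which(is.na(match(as.integer(expected), as.integer(m_start))))[1L]
      stop(sprintf("monthly table is not contiguous: missing %s",
                   format(expected[miss_i], "%Y-%m")))
    }
  }
  last_start <- m_start[length(m_start)]
  m_end <- seq(last_start, by = "1 month", length.out = 2L)[2L] - 1L
  # all Thursdays inside [first month start, last month end]
  first_th <- m_start[1L] + (4L - as.integer(format(m_start[1L], "%u"))) %% 7L
  thursdays <- seq(first_th, m_end, by = 7L)
  if (method == "repeat") {
    key <- format(thursdays, "%Y-%m")
    vals <- monthly$value[match(key, format(m_start, "%Y-%m"))]
    if (anyNA(vals)) stop("internal: Thursday outside monthly span")
  } else {
    days_in_month <- as.integer(c(m_start[-1L], m_end + 1L) - m_start)
    midpoints <- as.numeric(m_start) + (days_in_month - 1) / 2
    if (nrow(monthly) == 1L) {
      vals <- rep(monthly$value, length(thursdays))
    } else {
      vals <- stats::approx(midpoints, monthly$value,
                            xout = as.numeric(thursdays), rule = 2)$y
    }
  }
  wk <- date_to_iso_week(thursdays)
  weekly_series(wk$iso_year, wk$iso_week, vals)
}
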