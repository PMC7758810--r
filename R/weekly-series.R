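#' Weekly time series
#'
#' The universal currency of the pipeline: a gap-free, strictly increasing
#' ISO-week-indexed sequence of real values (counts, proportions or scores).
#'
#' @param iso_year,iso_week integer vectors identifying consecutive ISO weeks
#' @param value numeric vector of the same length; must be finite
#' @return object of class `weekly_series`
#' @export
weekly_series <- function(iso_year, iso_week, value) {
  iso_year <- as.integer(iso_year)
  iso_week <- as.integer(iso_week)
  value <- as.numeric(value)
  n <- length(value)
  if (n < 1L) stop("a weekly series must have length >= 1")
  if (length(iso_year) != n || length(iso_week) != n) {
    stop("iso_year, iso_week and value must have equal length")
  }
  if (any(!is.finite(value))) {
    stop(sprintf("non-finite value at week %s",
                 week_label(iso_year[!is.finite(value)][1L],
                            iso_week[!is.finite(value)][1L])))
  }
  th <- iso_week_thursday(iso_year, iso_week)
  if (n > 1L) {
    d <- diff(as.integer(th))
    if (any(d <= 0L)) stop("weeks must be strictly increasing")
    if (any(d != 7L)) {
      i <- which(d != 7L)[1L]
      miss <- date_to_iso_week(th[i] + 7L * seq_len(d[i] %/% 7L - 1L))
      stop(sprintf("gap in weekly coverage: missing %s",
                   paste(week_label(miss$iso_year, miss$iso_week),
                         collapse = ", ")))
    }
  }
  structure(list(iso_year = iso_year, iso_week = iso_week, value = value),
            class = "weekly_series")
}

#' @export
length.weekly_series <- function(x) length(x$value)

#' @export
print.weekly_series <- function(x, ...) {
  n <- length(x)
  cat(sprintf("<weekly_series> %d weeks: %s .. %s\n", n,
              week_label(x$iso_year[1L], x$iso_week[1L]),
              week_label(x$iso_year[n], x$iso_week[n])))
  cat(sprintf("  values: mean %.3f, range [%.3f, %.3f]\n",
              mean(x$value), min(x$value), max(x$value)))
  invisible(x)
}

#' @export
as.data.frame.weekly_series <- function(x, ...) {
  data.frame(week = week_label(x$iso_year, x$iso_week), value = x$value,
             stringsAsFactors = FALSE)
}

#' Subset a weekly series by position, keeping contiguity
#' @param series a `weekly_series`
#' @param i integer positions (must be consecutive)
#' @return `weekly_series`
#' @export
ws_slice <- function(series, i) {
  weekly_series(series$iso_year[i], series$iso_week[i], series$value[i])
}

#' Look up series values on given weeks
#'
#' @param series a `weekly_series`
#' @param iso_year,iso_week weeks to look up
#' @return numeric vector; error if any week is outside the series
#' @export
ws_value_at <- function(series, iso_year, iso_week) {
  pos <- ws_position(series, iso_year, iso_week)
  if (anyNA(pos)) {
    i <- which(is.na(pos))[1L]
    stop(sprintf("week %s not covered by the series",
                 week_label(iso_year[i], iso_week[i])))
  }
  series$value[pos]
}

# 1-based position of weeks within the series, NA if outside
ws_position <- function(series, iso_year, iso_week) {
  off <- as.integer(iso_week_thursday(iso_year, iso_week) -
                      iso_week_thursday(series$iso_year[1L], series$iso_week[1L])) %/% 7L
  pos <- off + 1L
  pos[pos < 1L | pos > length(series)] <- NA_integer_
  pos
}

#' First and last week of a series
#' @param series a `weekly_series`
#' @return list with `start` and `end`, each c(iso_year, iso_week)
#' @export
ws_span <- function(series) {
  n <- length(series)
  list(start = c(series$iso_year[1L], series$iso_week[1L]),
       end = c(series$iso_year[n], series$iso_week[n]))
}

#' Named data stream riding on the weekly grid
#'
#' A proxy stream with its provenance category (which drives ensemble
#' membership), native frequency, and — for monthly streams — the raw monthly
#' table it was aligned from.
#'
#' @param name stream name (unique within a panel)
#' @param category one of `historical_fatalities`, `health_services`, `online`,
#'   `economic`, `meteorological`
#' @param frequency `weekly` or `monthly`
#' @param series aligned `weekly_series`
#' @param monthly optional data.frame (year, month, value) for monthly streams
#' @return object of class `source_stream`
#' @export
source_stream <- function(name, category, frequency = "weekly", series,
                          monthly = NULL) {
  category <- match.arg(category, c("historical_fatalities", "health_services",
                                    "online", "economic", "meteorological"))
  frequency <- match.arg(frequency, c("weekly", "monthly"))
  stopifnot(inherits(series, "weekly_series"), is.character(name),
            nzchar(name))
  structure(list(name = name, category = category, frequency = frequency,
                 series = series, monthly = monthly, span = ws_span(series)),
            class = "source_stream")
}

#' @export
print.source_stream <- function(x, ...) {
  cat(sprintf("<source_stream> %s [%s, %s] %s .. %s (%d weeks)\n",
              x$name, x$category, x$frequency,
              week_label(x$span$start[1], x$span$start[2]),
              week_label(x$span$end[1], x$span$end[2]),
              length(x$series)))
  invisible(x)
}

#' Common coverage of a panel of streams
#'
#' @param streams list of `source_stream`
#' @param policy `intersect` (latest start / earliest end across streams; error
#'   on empty intersection) or `per_source` (each stream keeps its own span, so
#'   short streams simply train on fewer years)
#' @return for `intersect`, a list with `start`/`end`; for `per_source`, a
#'   named list of such spans
#' @export
common_span <- function(streams, policy = c("per_source", "intersect")) {
  policy <- match.arg(policy)
  stopifnot(length(streams) >= 1L)
  spans <- lapply(streams, function(s) s$span)
  names(spans) <- vapply(streams, function(s) s$name, "")
  if (policy == "per_source") return(spans)
  starts <- vapply(spans, function(sp)
    as.numeric(iso_week_thursday(sp$start[1], sp$start[2])), 0)
  ends <- vapply(spans, function(sp)
    as.numeric(iso_week_thursday(sp$end[1], sp$end[2])), 0)
  start <- max(starts)
  end <- min(ends)
  if (start > end) stop("streams have no overlapping weekly coverage")
  s <- date_to_iso_week(as.Date(start, origin = "1970-01-01"))
  e <- date_to_iso_week(as.Date(end, origin = "1970-01-01"))
  list(start = c(s$iso_year, s$iso_week), end = c(e$iso_year, e$iso_week))
}
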