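#' Surveillance evaluation metrics
#'
#' The metric battery used throughout: Pearson correlation (week-to-week trend
#' tracking), RMSE (weekly error magnitude), MAPE and symmetric MAPE (relative
#' weekly error), and the percentage error of the annual estimated rate per
#' 100,000 (whole-year accuracy, the headline surveillance quantity).
#'
#' @name evaluation
NULL

# align two weekly series on their (identical) calendars, returning values
align_pair <- function(actual, estimate) {
  stopifnot(inherits(actual, "weekly_series"), inherits(estimate, "weekly_series"))
  if (length(actual) != length(estimate) ||
      !identical(actual$iso_year, estimate$iso_year) ||
      !identical(actual$iso_week, estimate$iso_week)) {
    stop("actual and estimate must share the same weekly calendar")
  }
  list(a = actual$value, e = estimate$value)
}

#' Pearson correlation between actual and estimated weekly series
#' @param actual,estimate [weekly_series()] on the same calendar
#' @return sample Pearson correlation coefficient
#' @export
pearson <- function(actual, estimate) {
  p <- align_pair(actual, estimate)
  if (stats::sd(p$a) == 0 || stats::sd(p$e) == 0) {
    stop("Pearson correlation undefined: constant input series")
  }
  stats::cor(p$a, p$e)
}

#' Root mean squared error
#' @inheritParams pearson
#' @return RMSE in the units of the target
#' @export
rmse <- function(actual, estimate) {
  p <- align_pair(actual, estimate)
  sqrt(mean((p$a - p$e)^2))
}

#' Mean absolute percentage error
#' @inheritParams pearson
#' @return MAPE in percent: `100 * mean(|a - e| / a)`
#' @export
mape <- function(actual, estimate) {
  p <- align_pair(actual, estimate)
  if (any(p$a <= 0)) stop("MAPE undefined: actual values must be > 0")
  100 * mean(abs(p$a - p$e) / p$a)
}

#' Symmetric mean absolute percentage error
#'
#' Two conventions circulate. The default, `half_sum`,
#' is `100 * mean(|a - e| / (a + e))`; `textbook` is
#' `100 * mean(2 * |a - e| / (a + e))`, exactly twice the former. The
#' `half_sum` form is the one consistent with published surveillance tables
#' where SMAPE is roughly half of MAPE.
#'
#' @inheritParams pearson
#' @param convention `"half_sum"` (default) or `"textbook"`
#' @return SMAPE in percent
#' @export
smape <- function(actual, estimate, convention = c("half_sum", "textbook")) {
  convention <- match.arg(convention)
  p <- align_pair(actual, estimate)
  denom <- p$a + p$e
  if (any(denom <= 0)) stop("SMAPE undefined: actual + estimate must be > 0")
  base <- 100 * mean(abs(p$a - p$e) / denom)
  if (convention == "textbook") 2 * base else base
}

#' Annual estimated rate per 100,000 and its percentage error
#'
#' `rate = sum(estimate) / population * 100000`;
#' `error% = 100 * |sum(estimate) - sum(actual)| / sum(actual)` (identical on
#' counts or rates since the population denominator cancels). Both series must
#' span whole ISO years.
#'
#' @inheritParams pearson
#' @param population rate denominator (> 0)
#' @param require_full_year check that the series covers whole ISO years
#' @return list with `rate_per_100k` and `error_pct`
#' @export
annual_rate_and_error <- function(actual, estimate, population,
                                  require_full_year = TRUE) {
  p <- align_pair(actual, estimate)
  stopifnot(population > 0)
  if (require_full_year) assert_full_years(actual)
  rate <- sum(p$e) / population * 1e5
  err <- 100 * abs(sum(p$e) - sum(p$a)) / sum(p$a)
  list(rate_per_100k = rate, error_pct = err)
}

assert_full_years <- function(series) {
  yrs <- unique(series$iso_year)
  counts <- table(series$iso_year)
  expected <- weeks_in_iso_year(as.integer(names(counts)))
  if (any(as.integer(counts) != expected)) {
    bad <- names(counts)[as.integer(counts) != expected][1L]
    stop(sprintf("series does not span the full ISO year %s (%d of %d weeks)",
                 bad, counts[[bad]],
                 weeks_in_iso_year(as.integer(bad))))
  }
  invisible(TRUE)
}

#' Full metric report for a prediction series
#'
#' All fields are kept at full precision; rounding to table precision happens
#' only at serialization (see [report_row()]). A two-sided t-based p-value for
#' the Pearson correlation is included for information only.
#'
#' @inheritParams annual_rate_and_error
#' @param smape_convention passed to [smape()]
#' @return list of class `metric_report` with `pearson_r`, `pearson_p`,
#'   `rmse`, `mape_pct`, `smape_pct`, `annual_rate_per_100k`,
#'   `annual_error_pct`, `n_weeks`, `smape_convention`
#' @export
build_report <- function(actual, estimate, population,
                         smape_convention = "half_sum",
                         require_full_year = TRUE) {
  r <- pearson(actual, estimate)
  n <- length(actual)
  tstat <- r * sqrt((n - 2) / max(1 - r^2, .Machine$double.eps))
  annual <- annual_rate_and_error(actual, estimate, population,
                                  require_full_year = require_full_year)
  structure(list(
    pearson_r = r,
    pearson_p = 2 * stats::pt(abs(tstat), df = n - 2, lower.tail = FALSE),
    rmse = rmse(actual, estimate),
    mape_pct = mape(actual, estimate),
    smape_pct = smape(actual, estimate, smape_convention),
    annual_rate_per_100k = annual$rate_per_100k,
    annual_error_pct = annual$error_pct,
    n_weeks = n,
    smape_convention = smape_convention), class = "metric_report")
}

#' @export
print.metric_report <- function(x, ...) {
  cat(sprintf(
    "<metric_report> r=%.3f RMSE=%.3f MAPE=%.3f%% SMAPE=%.3f%% rate=%.2f/100k (err %.2f%%) [%d weeks]\n",
    x$pearson_r, x$rmse, x$mape_pct, x$smape_pct, x$annual_rate_per_100k,
    x$annual_error_pct, x$n_weeks))
  invisible(x)
}

#' Serialize a metric report as one table row
#'
#' Applies table-style rounding: 3 decimals for correlation, RMSE, MAPE and
#' SMAPE; 2 decimals for the annual rate and its error.
#'
#' @param label row label
#' @param report a [build_report()] result
#' @return one-row data.frame with columns `label`, `pearson`, `rmse`,
#'   `mape_pct`, `smape_pct`, `annual_rate`, `annual_error_pct`
#' @export
report_row <- function(label, report) {
  data.frame(label = label,
             pearson = round(report$pearson_r, 3),
             rmse = round(report$rmse, 3),
             mape_pct = round(report$mape_pct, 3),
             smape_pct = round(report$smape_pct, 3),
             annual_rate = round(report$annual_rate_per_100k, 2),
             annual_error_pct = round(report$annual_error_pct, 2),
             stringsAsFactors = FALSE)
}

#' Maximum pairwise gap of a metric across labelled reports
#'
#' @param reports either a named list of `metric_report` objects or a
#'   data.frame with a `label` column and one column per metric (e.g. a table
#'   of published results)
#' @param metric metric/column name
#' @return list with `gap` (max value minus min value) and `pair`
#'   (labels attaining it, max first)
#' @export
metric_gap <- function(reports, metric) {
  if (is.data.frame(reports)) {
    if (!metric %in% names(reports)) stop(sprintf("unknown metric '%s'", metric))
    vals <- reports[[metric]]
    labels <- reports$label
  } else {
    field <- switch(metric, pearson = "pearson_r", rmse = "rmse",
                    mape_pct = "mape_pct", smape_pct = "smape_pct",
                    annual_rate = "annual_rate_per_100k",
                    annual_error_pct = "annual_error_pct",
                    stop(sprintf("unknown metric '%s'", metric)))
    vals <- vapply(reports, function(r) r[[field]], 0)
    labels <- names(reports)
  }
  if (length(vals) < 2L) stop("need at least two reports")
  i_max <- which.max(vals)
  i_min <- which.min(vals)
  list(gap = vals[i_max] - vals[i_min],
       pair = c(labels[i_max], labels[i_min]))
}

#' Difference of one metric between two labelled rows of a results table
#'
#' Convenience for in-text comparison statistics ("model A improves on model B
#' by x"): returns `table[metric][from] - table[metric][to]`.
#'
#' @param table data.frame with a `label` column
#' @param metric column name
#' @param from,to row labels
#' @return numeric difference
#' @export
report_difference <- function(table, metric, from, to) {
  stopifnot(is.data.frame(table), metric %in% names(table))
  i <- match(from, table$label)
  j <- match(to, table$label)
  if (is.na(i)) stop(sprintf("no row labelled '%s'", from))
  if (is.na(j)) stop(sprintf("no row labelled '%s'", to))
  table[[metric]][i] - table[[metric]][j]
}

#' Plot actual vs estimated weekly counts
#'
#' Line plot of the two series over calendar time with an optional shaded
#' uncertainty band around the estimate.
#'
#' @param actual,estimate [weekly_series()] on the same calendar
#' @param ci optional list with `lower` and `upper` numeric vectors (same
#'   length as the series) bracketing the estimate
#' @param path output image path (device chosen from the extension)
#' @return `path`, invisibly
#' @export
plot_estimates <- function(actual, estimate, ci = NULL, path) {
  p <- align_pair(actual, estimate)
  date <- iso_week_thursday(actual$iso_year, actual$iso_week)
  df <- data.frame(date = rep(date, 2L),
                   value = c(p$a, p$e),
                   series = rep(c("actual", "estimated"), each = length(date)))
  gg <- ggplot2::ggplot(df, ggplot2::aes(x = .data$date, y = .data$value,
                                         colour = .data$series))
  if (!is.null(ci)) {
    stopifnot(length(ci$lower) == length(date), length(ci$upper) == length(date))
    band <- data.frame(date = date, lower = ci$lower, upper = ci$upper)
    gg <- gg + ggplot2::geom_ribbon(
      data = band,
      ggplot2::aes(x = .data$date, ymin = .data$lower, ymax = .data$upper),
      inherit.aes = FALSE, fill = "grey80")
  }
  gg <- gg + ggplot2::geom_line() +
    ggplot2::labs(x = NULL, y = "weekly count", colour = NULL) +
    ggplot2::theme_minimal()
  ggplot2::ggsave(path, gg, width = 9, height = 4, dpi = 120)
  invisible(path)
}
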