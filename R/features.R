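#' Lagged sliding-window feature matrices
#'
#' Each row corresponds to one target week `t` and contains `window`
#' consecutive values of the input series ending at week `t - lead`, oldest
#' first. Real-time streams use `lead = 0` (the same-week value is the last
#' column); the lagged historical-fatalities source uses a large lead
#' reflecting its reporting delay. By construction no row can reference any
#' week after `t - lead` — the leakage-free contract of a nowcast.
#'
#' @param series a [weekly_series()]
#' @param window number of consecutive weeks per row (>= 1)
#' @param lead gap, in weeks, between the newest feature and the target week
#'   (>= 0)
#' @param target_weeks optional data.frame (`iso_year`, `iso_week`) of target
#'   weeks; defaults to every week of `series` with sufficient history
#' @param source_name name used to prefix feature columns
#' @return object of class `feature_matrix`: list with `X` (numeric matrix,
#'   one row per target week, columns named `<source>_lag<k>` with `k` the lag
#'   behind the target), `iso_year`, `iso_week`, `source_name`
#' @export
build_lagged_features <- function(series, window = 8L, lead = 0L,
                                  target_weeks = NULL,
                                  source_name = "source") {
  stopifnot(inherits(series, "weekly_series"), window >= 1L, lead >= 0L)
  window <- as.integer(window)
  lead <- as.integer(lead)
  if (is.null(target_weeks)) {
    first <- window + lead
    if (first > length(series)) {
      stop("series too short for the requested window and lead")
    }
    idx <- first:length(series)
    target_weeks <- data.frame(iso_year = series$iso_year[idx],
                               iso_week = series$iso_week[idx])
  }
  pos <- ws_position(series, target_weeks$iso_year, target_weeks$iso_week)
  earliest <- pos - lead - window + 1L
  bad <- is.na(pos) | earliest < 1L | (pos - lead) > length(series)
  if (any(bad)) {
    feasible_pos <- window + lead
    feas <- if (feasible_pos <= length(series)) {
      week_label(series$iso_year[feasible_pos], series$iso_week[feasible_pos])
    } else "none"
    stop(sprintf(
      "insufficient history for target week %s (first feasible target: %s)",
      week_label(target_weeks$iso_year[bad][1L], target_weeks$iso_week[bad][1L]),
      feas))
  }
  lags <- (lead + window - 1L):lead  # oldest column first
  X <- vapply(lags, function(k) series$value[pos - k],
              numeric(length(pos)))
  X <- matrix(X, nrow = length(pos),
              dimnames = list(NULL, paste0(source_name, "_lag", lags)))
  structure(list(X = X, iso_year = as.integer(target_weeks$iso_year),
                 iso_week = as.integer(target_weeks$iso_week),
                 source_name = source_name),
            class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("<feature_matrix> %s: %d weeks x %d features (%s .. %s)\n",
              x$source_name, nrow(x$X), ncol(x$X),
              week_label(x$iso_year[1L], x$iso_week[1L]),
              week_label(x$iso_year[nrow(x$X)], x$iso_week[nrow(x$X)])))
  invisible(x)
}

# subset a feature matrix by row positions
fm_slice <- function(fm, i) {
  structure(list(X = fm$X[i, , drop = FALSE], iso_year = fm$iso_year[i],
                 iso_week = fm$iso_week[i], source_name = fm$source_name),
            class = "feature_matrix")
}

#' Year-blocked train / validation / test split specification
#'
#' Mirrors the protocol of holding out the final year for testing, the
#' previous year for validation, and everything earlier for training.
#'
#' @param train_through last training year (everything `<=` goes to training)
#' @param validation_year the validation year (must be `train_through + 1`)
#' @param test_year the held-out test year (must be `validation_year + 1`)
#' @return list of class `split_spec`
#' @export
split_spec <- function(train_through, validation_year, test_year) {
  if (!(train_through < validation_year && validation_year < test_year)) {
    stop("years must satisfy train_through < validation_year < test_year")
  }
  if (validation_year != train_through + 1 || test_year != validation_year + 1) {
    stop("split years must be contiguous")
  }
  structure(list(train_through = as.integer(train_through),
                 validation_year = as.integer(validation_year),
                 test_year = as.integer(test_year)),
            class = "split_spec")
}

#' Split a feature matrix and its target by ISO year
#'
#' Partitions rows by the ISO year of the target week: training years are
#' `<= train_through`, then the validation year, then the test year. Rows
#' beyond the test year are an error (the split must be a partition).
#'
#' @param features a [build_lagged_features()] result
#' @param target a [weekly_series()] covering all target weeks
#' @param spec a [split_spec()]
#' @return list with `train`, `validation`, `test`; each a list of `features`
#'   (feature_matrix) and `target` (numeric vector aligned to its rows)
#' @export
split_by_years <- function(features, target, spec) {
  stopifnot(inherits(features, "feature_matrix"), inherits(spec, "split_spec"))
  y <- ws_value_at(target, features$iso_year, features$iso_week)
  yr <- features$iso_year
  if (any(yr > spec$test_year)) {
    stop(sprintf("target weeks extend past the test year (%d)", spec$test_year))
  }
  blocks <- list(train = which(yr <= spec$train_through),
                 validation = which(yr == spec$validation_year),
                 test = which(yr == spec$test_year))
  for (b in names(blocks)) {
    if (length(blocks[[b]]) == 0L) {
      year_desc <- switch(b, train = paste("<=", spec$train_through),
                          validation = spec$validation_year,
                          test = spec$test_year)
      stop(sprintf("empty %s block (no target weeks in year %s)", b, year_desc))
    }
  }
  lapply(blocks, function(i) {
    list(features = fm_slice(features, i), target = y[i])
  })
}

#' Standardize feature matrices with train-fitted parameters
#'
#' Per-column affine transform (center, scale) fitted on the training matrix
#' only and applied to all matrices. The scale is the denominator-n standard
#' deviation, so training columns come out with mean 0 and SD exactly 1.
#' Constant columns are centered only and flagged in the scaler record.
#'
#' @param train training `feature_matrix`
#' @param others list of further `feature_matrix` objects (same width)
#' @return list with `train`, `others` (scaled copies) and `scaler`
#'   (`center`, `scale`, `constant` logical flags)
#' @export
standardize_features <- function(train, others = list()) {
  stopifnot(inherits(train, "feature_matrix"), nrow(train$X) >= 1L)
  for (o in others) {
    if (ncol(o$X) != ncol(train$X)) {
      stop(sprintf("width mismatch: train has %d columns, other has %d",
                   ncol(train$X), ncol(o$X)))
    }
  }
  n <- nrow(train$X)
  center <- colMeans(train$X)
  scale <- sqrt(colMeans(train$X^2) - center^2)  # denominator-n SD
  constant <- scale <= 0
  scale[constant] <- 1
  scaler <- list(center = center, scale = scale, constant = constant)
  apply_one <- function(fm) {
    fm$X <- sweep(sweep(fm$X, 2L, center, "-"), 2L, scale, "/")
    fm
  }
  list(train = apply_one(train), others = lapply(others, apply_one),
       scaler = scaler)
}

#' Invert a scaler on a matrix (round-trip check helper)
#' @param X scaled numeric matrix
#' @param scaler the `scaler` record from [standardize_features()]
#' @return matrix on the original scale
#' @export
unstandardize <- function(X, scaler) {
  sweep(sweep(X, 2L, scaler$scale, "*"), 2L, scaler$center, "+")
}
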