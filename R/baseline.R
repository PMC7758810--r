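#' Historical-fatalities baseline models
#'
#' Official mortality counts arrive with a delay of a year or more, so the
#' "contemporary practice" baseline estimates the current week from its own
#' history only: either regression on year-old lagged values of the target
#' (lead = 52 weeks by default, the optimistic edge of the reporting delay),
#' or an additive Holt-Winters model with period 52 that extrapolates level,
#' trend and seasonality.
#'
#' @name baseline
NULL

# Fit additive Holt-Winters with period 52 on the series up to (and
# including) `through_year`. Observations in ISO week 53 are folded out of the
# fit (the seasonal index has 52 slots); their predictions reuse week 52's
# seasonal slot. A constant series short-circuits to a trivial level model.
fit_hw <- function(series, through_year) {
  keep <- series$iso_year <= through_year & series$iso_week <= 52L
  vals <- series$value[keep]
  yrs <- series$iso_year[keep]
  if (length(unique(yrs)) < 2L) {
    stop("Holt-Winters needs at least 2 full seasonal cycles of history")
  }
  last_year <- max(yrs)
  last_week <- max(series$iso_week[keep & series$iso_year == last_year])
  if (stats::sd(vals) == 0) {
    return(list(kind = "holt_winters", trivial = TRUE, level = vals[1L],
                last = c(last_year, last_week)))
  }
  fit <- stats::HoltWinters(stats::ts(vals, frequency = 52L),
                            seasonal = "additive")
  list(kind = "holt_winters", trivial = FALSE, fit = fit,
       last = c(last_year, last_week))
}

# forecast values for the requested weeks; week 53 reuses week 52's forecast
hw_lookup <- function(m, iso_year, iso_week) {
  eff_week <- pmin(iso_week, 52L)
  # position of each (year, eff_week) in the 52-slot timeline after training
  steps <- (iso_year - m$last[1L]) * 52L + (eff_week - m$last[2L])
  if (any(steps < 1L)) {
    stop(sprintf("Holt-Winters can only forecast past its training end (%s)",
                 week_label(m$last[1L], m$last[2L])))
  }
  if (m$trivial) return(rep(m$level, length(steps)))
  fc <- stats::predict(m$fit, n.ahead = max(steps))
  as.numeric(fc)[steps]
}

#' Fit the historical-fatalities baseline
#'
#' Trains three baseline variants — OLS and RBF support vector regression on
#' lagged windows of the target itself (delayed by `lead` weeks), plus
#' additive Holt-Winters with period 52 — selects the best by validation-year
#' Pearson correlation, refits the winner on train + validation, and predicts
#' the test year.
#'
#' @param target_history the target [weekly_series()] (full history)
#' @param split a [split_spec()]
#' @param window lagged-window width for the regression variants
#' @param lead reporting delay in weeks (default 52)
#' @param svr_grid hyperparameter grid for the SVR variant
#' @param population rate denominator for validation metrics
#' @param criterion selection metric
#' @param smape_convention passed to [build_report()]
#' @param seed seed recorded on the model specs
#' @return a `source_model_result` with `source_name = "historical"`
#' @export
fit_baseline_historical <- function(target_history, split, window = 8L,
                                    lead = 52L,
                                    svr_grid = list(cost = c(1, 10, 100),
                                                    epsilon = c(0.1, 1)),
                                    population = 325700000,
                                    criterion = "pearson",
                                    smape_convention = "half_sum",
                                    seed = 1L) {
  stopifnot(inherits(target_history, "weekly_series"),
            inherits(split, "split_spec"))
  n_train_years <- length(unique(
    target_history$iso_year[target_history$iso_year <= split$train_through]))
  if (n_train_years < 2L) {
    stop("insufficient history: need >= 2 full years before the validation year")
  }
  stream <- source_stream("historical", "historical_fatalities", "weekly",
                          target_history)
  fm <- build_lagged_features(stream$series, window = window, lead = lead,
                              source_name = "historical")
  blocks <- split_by_years(fm, target_history, split)
  sc <- standardize_features(blocks$train$features,
                             list(blocks$validation$features,
                                  blocks$test$features))
  specs <- list(model_spec("ols", seed = seed),
                model_spec("svr", svr_grid, seed = seed))
  candidates <- fit_candidates(list(features = sc$train,
                                    target = blocks$train$target), specs)
  # Holt-Winters candidate: fitted on raw history through the training years
  hw_cand <- tryCatch(
    structure(list(family = "holt_winters", hyper = list(),
                   model = fit_hw(target_history, split$train_through),
                   failed = FALSE, width = NULL, seed = seed),
              class = "nowcast_candidate"),
    error = function(e) structure(
      list(family = "holt_winters", hyper = list(), model = NULL,
           failed = TRUE, message = conditionMessage(e), width = NULL,
           seed = seed), class = "nowcast_candidate"))
  candidates <- c(candidates, list(hw_cand))
  # HW predicts straight off the calendar, so give it the raw validation frame
  val_fm_raw <- blocks$validation$features
  sel_scores <- select_best_mixed(candidates, sc$others[[1L]], val_fm_raw,
                                  blocks$validation$target, criterion)
  chosen <- sel_scores$best
  # refit winner on train + validation, predict test
  if (chosen$family == "holt_winters") {
    model <- structure(list(family = "holt_winters", hyper = list(),
                            model = fit_hw(target_history,
                                           split$validation_year),
                            failed = FALSE, width = NULL, seed = seed),
                       class = "nowcast_candidate")
    test_fm <- blocks$test$features
  } else {
    tv_fm <- fm_slice(fm, seq_len(nrow(blocks$train$features$X) +
                                    nrow(blocks$validation$features$X)))
    test_rows <- (nrow(tv_fm$X) + 1L):nrow(fm$X)
    sc2 <- standardize_features(tv_fm, list(fm_slice(fm, test_rows)))
    tv_y <- c(blocks$train$target, blocks$validation$target)
    model <- fit_candidates(list(features = sc2$train, target = tv_y),
                            list(model_spec_from(chosen)))[[1L]]
    if (model$failed) model <- chosen
    test_fm <- sc2$others[[1L]]
  }
  test_pred <- predict_weekly(model, test_fm)
  val_actual <- weekly_series(val_fm_raw$iso_year, val_fm_raw$iso_week,
                              blocks$validation$target)
  validation_metrics <- build_report(val_actual, sel_scores$validation_predictions,
                                     population,
                                     smape_convention = smape_convention)
  structure(list(source_name = "historical",
                 category = "historical_fatalities",
                 family = chosen$family, hyper = chosen$hyper,
                 model = model,
                 validation_metrics = validation_metrics,
                 validation_predictions = sel_scores$validation_predictions,
                 test_predictions = test_pred,
                 ranking = sel_scores$ranking),
            class = "source_model_result")
}

# like select_best() but lets the Holt-Winters candidate predict from the raw
# (unstandardized) calendar frame while feature models use the scaled one
select_best_mixed <- function(candidates, val_fm_scaled, val_fm_raw, val_y,
                              criterion) {
  actual <- weekly_series(val_fm_raw$iso_year, val_fm_raw$iso_week, val_y)
  rows <- lapply(seq_along(candidates), function(i) {
    cc <- candidates[[i]]
    if (cc$failed) {
      return(data.frame(i = i, family = cc$family,
                        hyper = hyper_label(cc$hyper), score = -Inf,
                        rmse = Inf))
    }
    fm_use <- if (cc$family == "holt_winters") val_fm_raw else val_fm_scaled
    pred <- predict_weekly(cc, fm_use)
    r <- tryCatch(pearson(actual, pred), error = function(e) -Inf)
    val_rmse <- rmse(actual, pred)
    score <- switch(criterion, pearson = r, rmse = -val_rmse,
                    mape = -mape(actual, pred), smape = -smape(actual, pred))
    data.frame(i = i, family = cc$family, hyper = hyper_label(cc$hyper),
               score = score, rmse = val_rmse)
  })
  ranking <- do.call(rbind, rows)
  ord <- order(-ranking$score, ranking$rmse, family_order[ranking$family],
               ranking$hyper)
  ranking <- ranking[ord, , drop = FALSE]
  best <- candidates[[ranking$i[1L]]]
  fm_use <- if (best$family == "holt_winters") val_fm_raw else val_fm_scaled
  list(best = best, ranking = ranking,
       validation_predictions = predict_weekly(best, fm_use))
}
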