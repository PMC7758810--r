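make_train <- function(n = 40, p = 3, seed = 1, target_fn = NULL) {
  set.seed(seed)
  X <- matrix(stats::rnorm(n * p), n, p,
              dimnames = list(NULL, paste0("s_lag", seq_len(p) - 1L)))
  y <- if (is.null(target_fn)) as.numeric(X %*% c(2, -1, 0.5)) + 3 else
    target_fn(X)
  wk <- week_seq(2015, 1, n)
  fm <- structure(list(X = X, iso_year = wk$iso_year, iso_week = wk$iso_week,
                       source_name = "s"), class = "feature_matrix")
  list(features = fm, target = y)
}

test_that("OLS interpolates an exactly linear target", {
  tr <- make_train()
  cand <- fit_candidates(tr, list(model_spec("ols")))[[1]]
  pred <- predict_weekly(cand, tr$features)
  expect_lt(max(abs(pred$value - tr$target)), 1e-8)
})

test_that("lasso with an enormous penalty predicts the training mean", {
  tr <- make_train()
  cand <- fit_candidates(tr, list(model_spec("lasso",
                                             list(lambda = 1e9))))[[1]]
  pred <- predict_weekly(cand, tr$features)
  expect_equal(pred$value, rep(mean(tr$target), length(tr$target)),
               tolerance = 1e-6)
})

test_that("random forest is deterministic under a fixed seed", {
  tr <- make_train(seed = 2)
  spec <- model_spec("random_forest", list(num_trees = 100, max_depth = 0),
                     seed = 99)
  p1 <- predict_weekly(fit_candidates(tr, list(spec))[[1]], tr$features)
  p2 <- predict_weekly(fit_candidates(tr, list(spec))[[1]], tr$features)
  expect_identical(p1$value, p2$value)
})

test_that("candidate prediction is pointwise: permuting rows permutes outputs", {
  tr <- make_train(seed = 3)
  for (family in list(model_spec("ols"),
                      model_spec("svr", list(cost = 10, epsilon = 0.1)))) {
    cand <- fit_candidates(tr, list(family))[[1]]
    fm <- tr$features
    # reversed-calendar frame with the same rows reversed
    rev_fm <- structure(list(X = fm$X[rev(seq_len(nrow(fm$X))), , drop = FALSE],
                             iso_year = fm$iso_year, iso_week = fm$iso_week,
                             source_name = "s"), class = "feature_matrix")
    straight <- predict_weekly(cand, fm)$value
    reversed <- predict_weekly(cand, rev_fm)$value
    expect_equal(rev(reversed), straight, tolerance = 1e-10)
  }
  empty <- structure(list(X = tr$features$X[0, , drop = FALSE],
                          iso_year = integer(), iso_week = integer(),
                          source_name = "s"), class = "feature_matrix")
  cand <- fit_candidates(tr, list(model_spec("ols")))[[1]]
  expect_error(predict_weekly(cand, empty), "empty feature matrix")
})

test_that("selection maximizes the criterion with deterministic tie-breaks", {
  tr <- make_train(seed = 4)
  val <- make_train(n = 20, seed = 5)
  good <- fit_candidates(tr, list(model_spec("ols")))[[1]]
  # a candidate predicting pure noise scores lower than OLS on this target
  noisy <- good
  noisy$model <- list(kind = "linear",
                      coef = c(100, 0, 0, 0))  # constant => Pearson sentinel
  sel <- select_best(list(noisy, good), val)
  expect_identical(sel$best$family, "ols")
  expect_false(any(!is.finite(sel$ranking$score[1])))
  # constant predictor ranks last via the -Inf sentinel
  expect_equal(sel$ranking$score[nrow(sel$ranking)], -Inf)
  # zoo dominance: winner's validation score >= every other candidate's
  cands <- fit_candidates(tr, small_specs())
  sel2 <- select_best(cands, val)
  expect_true(all(sel2$ranking$score[1] >= sel2$ranking$score))
})

test_that("exact Pearson ties break on lower validation RMSE", {
  val <- make_train(n = 20, seed = 6)
  # two linear candidates with identical correlation, one biased (worse RMSE)
  beta <- c(3, 2, -1, 0.5)
  exact <- structure(list(family = "ols", hyper = list(),
                          model = list(kind = "linear", coef = beta),
                          failed = FALSE, width = 3, seed = 1),
                     class = "nowcast_candidate")
  biased <- exact
  biased$model$coef[1] <- beta[1] + 50  # same r, RMSE worse by 50
  sel <- select_best(list(biased, exact), val)
  expect_equal(sel$best$model$coef, beta)
})

test_that("failed candidates degrade gracefully and all-failed aborts", {
  tr <- make_train(seed = 7, target_fn = function(X) rep(5, nrow(X)))
  # constant target: glmnet refuses (zero-variance y) but OLS still fits,
  # so the source survives with the lasso candidate flagged failed
  cands <- fit_candidates(tr, list(model_spec("lasso", list(lambda = 1)),
                                   model_spec("ols")))
  expect_true(cands[[1]]$failed)
  expect_false(cands[[2]]$failed)
  expect_match(cands[[1]]$message, ".")
  # every candidate failing is fatal
  expect_error(fit_candidates(tr, list(model_spec("lasso", list(lambda = 1)))),
               "every candidate failed")
})

test_that("validation metrics stored on a source result are recomputable", {
  truth <- generate_truth(truth_config(), seed = 14)
  st <- oracle_stream(truth, sigma = 40, seed = 14)
  res <- fit_source_model(st, truth, default_split(), specs = small_specs(),
                          window = 4)
  vp <- res$validation_predictions
  actual <- weekly_series(vp$iso_year, vp$iso_week,
                          ws_value_at(truth, vp$iso_year, vp$iso_week))
  re <- build_report(actual, vp, 325700000)
  expect_identical(re$pearson_r, res$validation_metrics$pearson_r)
  expect_identical(re$rmse, res$validation_metrics$rmse)
  expect_identical(re$annual_error_pct,
                   res$validation_metrics$annual_error_pct)
  # prediction calendars match the split exactly
  expect_true(all(res$test_predictions$iso_year == 2017))
  expect_length(res$test_predictions, 52L)
})

test_that("Holt-Winters nails a noise-free seasonal series and handles
           constants", {
  truth <- smooth_truth()   # noise-free seasonal + trend
  base <- fit_baseline_historical(truth, default_split(), seed = 1)
  actual <- weekly_series(base$test_predictions$iso_year,
                          base$test_predictions$iso_week,
                          ws_value_at(truth, base$test_predictions$iso_year,
                                      base$test_predictions$iso_week))
  expect_lt(mape(actual, base$test_predictions), 1)
  # constant history forecasts the constant with zero error
  const <- toy_series(rep(500, 209), year = 2014L)
  hw <- mortalitynowcast:::fit_hw(const, 2015)
  pred <- mortalitynowcast:::hw_lookup(hw, rep(2016L, 5), 1:5)
  expect_equal(pred, rep(500, 5))
})

test_that("lag-52 OLS recovers a pure linear trend to near machine precision", {
  tc <- truth_config(trend_per_week = 1, seasonal_amplitude = 0,
                     noise_sd = 0, surge_per_week = 0)
  truth <- generate_truth(tc, seed = 1)
  fm <- build_lagged_features(truth, window = 2, lead = 52,
                              source_name = "historical")
  blocks <- split_by_years(fm, truth, default_split())
  cand <- fit_candidates(blocks$train, list(model_spec("ols")))[[1]]
  pred <- predict_weekly(cand, blocks$test$features)
  expect_lt(max(abs(pred$value - blocks$test$target)), 1e-6)
})

test_that("baseline requires at least two years of history", {
  short <- generate_truth(truth_config(n_years = 3, start = c(2015L, 1L),
                                       surge_per_week = 0), seed = 1)
  expect_error(fit_baseline_historical(short,
                                       split_spec(2015, 2016, 2017)),
               "insufficient history")
})
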