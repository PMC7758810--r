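# build a fake source_model_result with given prediction series
fake_result <- function(name, val_pred, test_pred, category = "online") {
  structure(list(source_name = name, category = category, family = "ols",
                 hyper = list(), model = NULL,
                 validation_predictions = val_pred,
                 test_predictions = test_pred),
            class = "source_model_result")
}

val_weeks <- function() week_seq(2016, 1, 52)
test_weeks <- function() week_seq(2017, 1, 52)

ws_on <- function(weeks, values) {
  weekly_series(weeks$iso_year, weeks$iso_week, values)
}

test_that("stacking assembles member predictions column by column", {
  wk <- week_seq(2016, 1, 3)
  r1 <- fake_result("a", ws_on(wk, c(1, 2, 3)), NULL)
  r2 <- fake_result("b", ws_on(wk, c(10, 20, 30)), NULL)
  st <- stack_predictions(list(r1, r2), wk, "validation")
  expect_equal(unname(st$X), cbind(c(1, 2, 3), c(10, 20, 30)))
  expect_equal(colnames(st$X), c("a", "b"))
  # single member: matrix equals that member's vector
  st1 <- stack_predictions(list(r1), wk, "validation")
  expect_equal(as.numeric(st1$X), c(1, 2, 3))
  # missing week errors naming member and week
  short <- fake_result("c", ws_on(week_seq(2016, 2, 2), c(5, 6)), NULL)
  expect_error(stack_predictions(list(r1, short), wk, "validation"),
               "member 'c' has no validation prediction for week 2016-W01")
})

test_that("the meta-learner recovers a single perfect member almost exactly", {
  set.seed(20)
  target_vals <- 850 + 30 * cos(2 * pi * (1:52) / 52) + stats::rnorm(52, 0, 20)
  target <- ws_on(val_weeks(), target_vals)
  member <- fake_result("perfect", target,
                        ws_on(test_weeks(), target_vals + 5))
  # capacity check: without regularization the network must be able to learn
  # the identity mapping (the default weight decay deliberately trades a
  # small shrinkage bias for variance reduction on realistic panels)
  failures <- 0L
  for (s in 1:5) {
    spec <- ensemble_spec("perfect", weight_decay = 0, seed = s)
    model <- fit_meta_learner(stack_predictions(list(member), val_weeks(),
                                                "validation"), target, spec)
    fitted <- predict_ensemble(model,
                               stack_predictions(list(member), val_weeks(),
                                                 "validation"))
    if (mape(target, fitted) >= 0.5) failures <- failures + 1L
  }
  expect_lte(failures, 1L)
})

test_that("two oppositely biased members are averaged below either's error", {
  set.seed(21)
  target <- ws_on(val_weeks(), 850 + stats::rnorm(52, 0, 30))
  up <- fake_result("up", ws_on(val_weeks(), target$value + 40), NULL)
  down <- fake_result("down", ws_on(val_weeks(), target$value - 40), NULL)
  stacked <- stack_predictions(list(up, down), val_weeks(), "validation")
  model <- fit_meta_learner(stacked, target, ensemble_spec(c("up", "down"),
                                                           seed = 1))
  fitted <- predict_ensemble(model, stacked)
  err <- rmse(target, fitted)
  expect_lte(err, 40)  # each member alone has validation RMSE exactly 40
})

test_that("zero-epoch networks are deterministic per seed; outputs finite on
           all-zero input", {
  target <- ws_on(val_weeks(), 800 + sin(1:52) * 30)
  member <- fake_result("m", target, NULL)
  stacked <- stack_predictions(list(member), val_weeks(), "validation")
  m1 <- fit_meta_learner(stacked, target, ensemble_spec("m", epochs = 0,
                                                        seed = 5))
  m2 <- fit_meta_learner(stacked, target, ensemble_spec("m", epochs = 0,
                                                        seed = 5))
  zeros <- stacked; zeros$X[] <- 0
  expect_identical(predict_ensemble(m1, stacked)$value,
                   predict_ensemble(m2, stacked)$value)
  expect_true(all(is.finite(predict_ensemble(m1, zeros)$value)))
  m3 <- fit_meta_learner(stacked, target, ensemble_spec("m", epochs = 0,
                                                        seed = 6))
  expect_false(identical(predict_ensemble(m1, stacked)$value,
                         predict_ensemble(m3, stacked)$value))
})

test_that("ensemble prediction is pointwise and width-checked", {
  target <- ws_on(val_weeks(), 800 + cos(1:52) * 25)
  member <- fake_result("m", target, NULL)
  stacked <- stack_predictions(list(member), val_weeks(), "validation")
  model <- fit_meta_learner(stacked, target, ensemble_spec("m", seed = 2))
  straight <- predict_ensemble(model, stacked)$value
  flipped <- stacked
  flipped$X <- stacked$X[rev(seq_len(52)), , drop = FALSE]
  expect_equal(rev(predict_ensemble(model, flipped)$value), straight,
               tolerance = 1e-12)
  wide <- stacked; wide$X <- cbind(stacked$X, stacked$X)
  expect_error(predict_ensemble(model, wide), "width mismatch")
})

test_that("the six canonical combinations are produced with correct membership", {
  set.seed(22)
  target_all <- generate_truth(truth_config(), seed = 22)
  mk <- function(name, category) {
    noise_v <- stats::rnorm(52, 0, 30)
    noise_t <- stats::rnorm(52, 0, 30)
    fake_result(name,
                ws_on(val_weeks(),
                      ws_value_at(target_all, val_weeks()$iso_year,
                                  val_weeks()$iso_week) + noise_v),
                ws_on(test_weeks(),
                      ws_value_at(target_all, test_weeks()$iso_year,
                                  test_weeks()$iso_week) + noise_t),
                category)
  }
  results <- list(poison = mk("poison", "health_services"),
                  lifeline = mk("lifeline", "health_services"),
                  ed = mk("ed", "health_services"),
                  google = mk("google", "online"),
                  youtube = mk("youtube", "online"),
                  reddit = mk("reddit", "online"),
                  twitter = mk("twitter", "online"))
  baseline <- mk("historical", "historical_fatalities")
  combos <- run_combinations(results, baseline, target_all, seed = 1,
                             epochs = 300)
  expect_length(combos, 6L)
  expect_false(any(vapply(combos, function(cb) isTRUE(cb$skipped), TRUE)))
  labels <- vapply(combos, function(cb) cb$label, "")
  expect_setequal(labels,
                  c("Health services data sources", "Online data sources",
                    "Baseline plus health services sources",
                    "Baseline plus online data sources",
                    "Health services plus online data sources",
                    "All data sources"))
  # all-sources membership = baseline + health + online
  all_members <- combos[["All data sources"]]$spec$member_sources
  expect_setequal(all_members,
                  c("historical", "poison", "lifeline", "ed",
                    "google", "youtube", "reddit", "twitter"))
  hs <- combos[["Health services data sources"]]$spec$member_sources
  on <- combos[["Online data sources"]]$spec$member_sources
  expect_setequal(all_members, union(c("historical", hs), on))
  # metrics stored on each result are recomputable from its predictions
  cb <- combos[["All data sources"]]
  actual <- ws_on(test_weeks(),
                  ws_value_at(target_all, test_weeks()$iso_year,
                              test_weeks()$iso_week))
  re <- build_report(actual, cb$test_predictions, 325700000)
  expect_identical(re$pearson_r, cb$test_metrics$pearson_r)
  expect_identical(re$rmse, cb$test_metrics$rmse)
})

test_that("combinations missing their members are skipped with a reason", {
  set.seed(23)
  target_all <- generate_truth(truth_config(), seed = 23)
  mk_hs <- function(name) {
    fake_result(name,
                ws_on(val_weeks(),
                      ws_value_at(target_all, val_weeks()$iso_year,
                                  val_weeks()$iso_week) + stats::rnorm(52, 0, 30)),
                ws_on(test_weeks(),
                      ws_value_at(target_all, test_weeks()$iso_year,
                                  test_weeks()$iso_week) + stats::rnorm(52, 0, 30)),
                "health_services")
  }
  results <- list(poison = mk_hs("poison"), ed = mk_hs("ed"))
  baseline <- fake_result("historical",
                          ws_on(val_weeks(),
                                ws_value_at(target_all, val_weeks()$iso_year,
                                            val_weeks()$iso_week) +
                                  stats::rnorm(52, 0, 30)),
                          ws_on(test_weeks(),
                                ws_value_at(target_all, test_weeks()$iso_year,
                                            test_weeks()$iso_week) +
                                  stats::rnorm(52, 0, 30)),
                          "historical_fatalities")
  combos <- run_combinations(results, baseline, target_all, seed = 2,
                             epochs = 200)
  skipped <- vapply(combos, function(cb) isTRUE(cb$skipped), TRUE)
  expect_true(skipped[["Online data sources"]])
  expect_match(combos[["Online data sources"]]$reason, "no member sources")
  expect_false(skipped[["Health services data sources"]])
  expect_false(skipped[["Baseline plus health services sources"]])
})

test_that("bootstrap intervals bracket most actual test weeks", {
  set.seed(24)
  target_all <- generate_truth(truth_config(), seed = 24)
  val_v <- ws_value_at(target_all, val_weeks()$iso_year, val_weeks()$iso_week)
  test_v <- ws_value_at(target_all, test_weeks()$iso_year,
                        test_weeks()$iso_week)
  member <- fake_result("m", ws_on(val_weeks(), val_v + stats::rnorm(52, 0, 25)),
                        ws_on(test_weeks(), test_v + stats::rnorm(52, 0, 25)))
  baseline <- fake_result("historical",
                          ws_on(val_weeks(), val_v + stats::rnorm(52, 0, 25)),
                          ws_on(test_weeks(), test_v + stats::rnorm(52, 0, 25)),
                          "historical_fatalities")
  combos <- run_combinations(list(m = member), baseline, target_all, seed = 3,
                             labels = "All data sources", epochs = 300)
  cb <- combos[["All data sources"]]
  ci <- ensemble_interval(cb, target_all, seed = 9)
  expect_true(all(ci$lower <= cb$test_predictions$value))
  expect_true(all(ci$upper >= cb$test_predictions$value))
  coverage <- mean(test_v >= ci$lower & test_v <= ci$upper)
  expect_gt(coverage, 0.6)
})
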