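#!/usr/bin/env Rscript
# Stage 2: phase-1 per-source models.
#
# For every weekly proxy stream: lagged sliding-window features (8 weeks,
# lead 0 — these signals are available in the target week itself), year-block
# split (train <= 2015, validate 2016, test 2017), the model zoo (OLS, lasso,
# ridge, elastic net, random forest, SVR), selection by validation-year
# Pearson correlation, refit on train + validation, test-year prediction.
# The historical baseline uses the target's own lag-52 features plus an
# additive Holt-Winters model with period 52.
#
# Writes results/phase1_table.csv plus per-source prediction CSVs that stage
# 3 stacks.

suppressMessages(library(mortalitynowcast))

seed <- 1L
data_dir <- file.path("results", "data")
pred_dir <- file.path("results", "phase1_predictions")
dir.create(pred_dir, recursive = TRUE, showWarnings = FALSE)

bundle <- read_bundle(data_dir)
split <- split_spec(2015, 2016, 2017)
specs <- default_model_specs(seed = derive_seed(seed, "zoo"))

fit_one <- function(stream) {
  fit_source_model(stream, bundle$truth, split, specs = specs,
                   population = bundle$population)
}
weekly_streams <- Filter(function(s)
  !s$category %in% c("economic", "meteorological"), bundle$streams)
results <- lapply(weekly_streams, fit_one)
baseline <- fit_baseline_historical(bundle$truth, split,
                                    population = bundle$population,
                                    seed = derive_seed(seed, "baseline"))

rows <- list()
manifest <- list()
for (r in c(list(baseline), unname(results))) {
  tp <- r$test_predictions
  actual <- weekly_series(tp$iso_year, tp$iso_week,
                          ws_value_at(bundle$truth, tp$iso_year, tp$iso_week))
  rep <- build_report(actual, tp, bundle$population)
  rows[[r$source_name]] <- cbind(report_row(r$source_name, rep)[, 1,
                                                                drop = FALSE],
                                 data.frame(category = r$category,
                                            family = r$family),
                                 report_row(r$source_name, rep)[, -1])
  write_series_csv(r$validation_predictions,
                   file.path(pred_dir, paste0(r$source_name, "_validation.csv")))
  write_series_csv(tp, file.path(pred_dir, paste0(r$source_name, "_test.csv")))
  manifest[[r$source_name]] <- list(category = r$category, family = r$family)
  cat(sprintf("%-14s -> %-13s validation r=%.3f, test MAPE=%.2f%%\n",
              r$source_name, r$family, r$validation_metrics$pearson_r,
              rep$mape_pct))
}
table1 <- do.call(rbind, rows)
utils::write.csv(table1, file.path("results", "phase1_table.csv"),
                 row.names = FALSE, quote = FALSE)
jsonlite::write_json(manifest, file.path(pred_dir, "sources.json"),
                     auto_unbox = TRUE, pretty = TRUE)
cat("\nwrote results/phase1_table.csv:\n")
print(table1, row.names = FALSE)
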