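#!/usr/bin/env Rscript
# Stage 3: phase-2 stacking ensembles.
#
# Reads the phase-1 weekly predictions written by stage 2, stacks them as
# inputs to the neural-network meta-learner (trained on validation-year
# predictions vs validation-year truth), and evaluates the six canonical
# source combinations on the held-out test year. Writes the ensemble
# performance table, the all-sources weekly predictions with a residual
# bootstrap band, and actual-vs-estimated plots for the baseline and the
# all-sources ensemble.

suppressMessages(library(mortalitynowcast))

seed <- 1L
data_dir <- file.path("results", "data")
pred_dir <- file.path("results", "phase1_predictions")

bundle <- read_bundle(data_dir)
manifest <- jsonlite::read_json(file.path(pred_dir, "sources.json"))

load_result <- function(name, meta) {
  structure(list(
    source_name = name, category = meta$category, family = meta$family,
    validation_predictions = read_series_csv(
      file.path(pred_dir, paste0(name, "_validation.csv"))),
    test_predictions = read_series_csv(
      file.path(pred_dir, paste0(name, "_test.csv")))),
    class = "source_model_result")
}
all_results <- Map(load_result, names(manifest), manifest)
baseline <- all_results$historical
results <- all_results[names(all_results) != "historical"]

combos <- run_combinations(results, baseline, bundle$truth,
                           population = bundle$population,
                           seed = derive_seed(seed, "ensemble"))

rows <- lapply(combos, function(cb) {
  if (isTRUE(cb$skipped)) {
    cat(sprintf("%-42s SKIPPED (%s)\n", cb$label, cb$reason))
    return(NULL)
  }
  report_row(cb$label, cb$test_metrics)
})
table2 <- do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
utils::write.csv(table2, file.path("results", "phase2_table.csv"),
                 row.names = FALSE, quote = FALSE)
cat("wrote results/phase2_table.csv:\n")
print(table2, row.names = FALSE)

all_cb <- combos[["All data sources"]]
tp <- all_cb$test_predictions
actual <- weekly_series(tp$iso_year, tp$iso_week,
                        ws_value_at(bundle$truth, tp$iso_year, tp$iso_week))
ci <- ensemble_interval(all_cb, bundle$truth,
                        seed = derive_seed(seed, "interval"))
pred_out <- data.frame(week = week_label(tp$iso_year, tp$iso_week),
                       actual = actual$value, estimate = tp$value,
                       ci_low = ci$lower, ci_high = ci$upper)
utils::write.csv(pred_out, file.path("results", "predictions_all_sources.csv"),
                 row.names = FALSE, quote = FALSE)
plot_estimates(actual, tp, ci = ci,
               path = file.path("results", "plot_all_sources.png"))

bp <- baseline$test_predictions
base_actual <- weekly_series(bp$iso_year, bp$iso_week,
                             ws_value_at(bundle$truth, bp$iso_year,
                                         bp$iso_week))
plot_estimates(base_actual, bp,
               path = file.path("results", "plot_baseline.png"))

cat(sprintf("\nall-sources ensemble: r=%.3f, annual error=%.2f%% (baseline: r=%.3f, %.2f%%)\n",
            all_cb$test_metrics$pearson_r,
            all_cb$test_metrics$annual_error_pct,
            pearson(base_actual, bp),
            build_report(base_actual, bp, bundle$population)$annual_error_pct))
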