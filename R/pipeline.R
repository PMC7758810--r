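#' Reproducible end-to-end pipeline run
#'
#' Orchestrates simulate -> fit -> ensemble -> report as one seeded run: a
#' synthetic bundle (or an external directory of stream CSVs plus a manifest)
#' goes through per-source phase-1 fitting, the six canonical stacking
#' ensembles, and metric tables. Reruns with the same config and seed are
#' byte-identical in every CSV the run writes.
#'
#' @name cli_pipeline
NULL

pipeline_defaults <- function() {
  list(
    data_dir = NULL,          # NULL => simulate
    out_dir = NULL,
    seed = 1L,
    population = 325700000,
    split = list(train_through = 2015L, validation_year = 2016L,
                 test_year = 2017L),
    window = 8L,
    lead = 0L,
    baseline_lead = 52L,
    standardize = TRUE,
    criterion = "pearson",
    smape_convention = "half_sum",
    refit = TRUE,
    include_economic = FALSE,  # economic/meteorological streams as members
    ensemble = list(hidden_units = 8L, activation = "relu", epochs = 2000L,
                    learning_rate = 0.01, weight_decay = 0.3),
    truth = list(),            # overrides for truth_config()
    log_level = "info"
  )
}

#' Validate and resolve a pipeline configuration
#'
#' Accepts a named list or a YAML file path. All defaults are filled in; all
#' problems are reported at once; unknown keys are rejected (typo safety).
#'
#' @param config named list or path to a YAML file
#' @return resolved config list of class `run_config`
#' @export
validate_config <- function(config = list()) {
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
    if (is.null(config)) config <- list()
  }
  stopifnot(is.list(config))
  defaults <- pipeline_defaults()
  errors <- character()
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown)) {
    errors <- c(errors, sprintf("unknown config key(s): %s",
                                paste(unknown, collapse = ", ")))
  }
  resolved <- utils::modifyList(defaults, config[setdiff(names(config), unknown)])
  for (nested in c("split", "ensemble")) {
    bad <- setdiff(names(resolved[[nested]]), names(defaults[[nested]]))
    if (length(bad)) {
      errors <- c(errors, sprintf("unknown %s key(s): %s", nested,
                                  paste(bad, collapse = ", ")))
    }
    resolved[[nested]] <- utils::modifyList(defaults[[nested]],
                                            resolved[[nested]])
  }
  sp <- resolved$split
  split_ok <- tryCatch({
    split_spec(sp$train_through, sp$validation_year, sp$test_year)
    TRUE
  }, error = function(e) {
    errors <<- c(errors, sprintf("split: %s", conditionMessage(e)))
    FALSE
  })
  if (is.null(resolved$out_dir)) errors <- c(errors, "out_dir is required")
  if (!is.numeric(resolved$population) || resolved$population <= 0) {
    errors <- c(errors, "population must be a positive number")
  }
  if (!is.numeric(resolved$window) || resolved$window < 1) {
    errors <- c(errors, "window must be >= 1")
  }
  if (length(errors)) {
    stop(paste(c("invalid configuration:", paste(" -", errors)),
               collapse = "\n"))
  }
  class(resolved) <- c("run_config", "list")
  resolved
}

pipe_log <- function(log_path, stage, event, detail = "") {
  line <- sprintf("%s | %s | %s", stage, event, detail)
  cat(line, "\n", sep = "", file = log_path, append = TRUE)
  invisible(line)
}

#' Run the full nowcasting pipeline
#'
#' Stages: `simulate` (skipped when `data_dir` points at existing CSVs),
#' `fit` (phase-1 per-source models plus the historical baseline),
#' `ensemble` (the six canonical combinations) and `report` (tables, weekly
#' prediction CSVs and plots). On error the stage name is reported and a
#' `FAILED` marker is left in the output directory alongside any partial
#' outputs.
#'
#' @param config a list / YAML path accepted by [validate_config()]
#' @return the output directory path, invisibly; the directory contains
#'   `phase1_table.csv`, `phase2_table.csv`, `predictions_all_sources.csv`,
#'   `predictions_baseline.csv`, plots, `resolved_config.yaml`, `run.log`
#' @export
run_pipeline <- function(config) {
  config <- validate_config(config)
  out_dir <- config$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(out_dir, "run.log")
  cat("", file = log_path)  # truncate
  stage <- "configure"
  result <- tryCatch({
    cfg_echo <- unclass(config)
    yaml::write_yaml(cfg_echo, file.path(out_dir, "resolved_config.yaml"))
    split <- split_spec(config$split$train_through,
                        config$split$validation_year,
                        config$split$test_year)

    stage <- "simulate"
    t0 <- Sys.time()
    if (is.null(config$data_dir)) {
      data_dir <- file.path(out_dir, "data")
      tc <- do.call(truth_config, config$truth)
      bundle <- generate_bundle(tc, population = config$population,
                                seed = derive_seed(config$seed, "simulate"))
      write_bundle(bundle, data_dir)
      pipe_log(log_path, stage, "done",
               sprintf("seed=%d streams=%d elapsed=%.1fs",
                       derive_seed(config$seed, "simulate"),
                       length(bundle$streams),
                       as.numeric(Sys.time() - t0, units = "secs")))
    } else {
      data_dir <- config$data_dir
      bundle <- read_bundle(data_dir)
      pipe_log(log_path, stage, "skipped",
               sprintf("using external data_dir=%s", data_dir))
    }

    stage <- "fit"
    t0 <- Sys.time()
    target <- bundle$truth
    # check coverage up front so the failure names the split stage clearly
    if (!any(target$iso_year == split$test_year)) {
      stop(sprintf("split_by_years: target has no weeks in test year %d",
                   split$test_year))
    }
    specs <- default_model_specs(seed = derive_seed(config$seed, "zoo"))
    results <- list()
    for (s in bundle$streams) {
      if (!config$include_economic &&
          s$category %in% c("economic", "meteorological")) {
        pipe_log(log_path, stage, "excluded",
                 sprintf("%s (%s)", s$name, s$category))
        next
      }
      res <- fit_source_model(
        s, target, split, specs = specs, window = config$window,
        lead = config$lead, standardize = config$standardize,
        criterion = config$criterion, population = config$population,
        refit = config$refit, smape_convention = config$smape_convention)
      results[[s$name]] <- res
      pipe_log(log_path, stage, "source",
               sprintf("%s -> %s(%s) val_r=%.3f", s$name, res$family,
                       hyper_label(res$hyper),
                       res$validation_metrics$pearson_r))
    }
    baseline <- fit_baseline_historical(
      target, split, window = config$window, lead = config$baseline_lead,
      population = config$population, criterion = config$criterion,
      smape_convention = config$smape_convention,
      seed = derive_seed(config$seed, "baseline"))
    pipe_log(log_path, stage, "baseline",
             sprintf("historical -> %s val_r=%.3f", baseline$family,
                     baseline$validation_metrics$pearson_r))
    pipe_log(log_path, stage, "done",
             sprintf("elapsed=%.1fs", as.numeric(Sys.time() - t0,
                                                 units = "secs")))

    stage <- "phase1_report"
    phase1 <- do.call(rbind, c(
      list(phase1_row(baseline, target, config)),
      lapply(results, function(r) phase1_row(r, target, config))))
    utils::write.csv(phase1, file.path(out_dir, "phase1_table.csv"),
                     row.names = FALSE, quote = FALSE)

    stage <- "ensemble"
    t0 <- Sys.time()
    combos <- run_combinations(
      results, baseline, target, population = config$population,
      seed = derive_seed(config$seed, "ensemble"),
      hidden_units = config$ensemble$hidden_units,
      activation = config$ensemble$activation,
      epochs = config$ensemble$epochs,
      learning_rate = config$ensemble$learning_rate,
      weight_decay = config$ensemble$weight_decay,
      smape_convention = config$smape_convention)
    pipe_log(log_path, stage, "done",
             sprintf("combinations=%d elapsed=%.1fs", length(combos),
                     as.numeric(Sys.time() - t0, units = "secs")))

    stage <- "report"
    rows <- lapply(combos, function(cb) {
      if (isTRUE(cb$skipped)) return(NULL)
      report_row(cb$label, cb$test_metrics)
    })
    phase2 <- do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
    utils::write.csv(phase2, file.path(out_dir, "phase2_table.csv"),
                     row.names = FALSE, quote = FALSE)
    skipped <- combos[vapply(combos, function(cb) isTRUE(cb$skipped), TRUE)]
    for (cb in skipped) {
      pipe_log(log_path, stage, "combination_skipped",
               sprintf("%s: %s", cb$label, cb$reason))
    }
    all_cb <- combos[["All data sources"]]
    if (!is.null(all_cb) && !isTRUE(all_cb$skipped)) {
      write_predictions_csv(all_cb$test_predictions, target,
                            file.path(out_dir, "predictions_all_sources.csv"))
      ci <- ensemble_interval(all_cb, target,
                              seed = derive_seed(config$seed, "interval"))
      plot_estimates(
        actual_on(target, all_cb$test_predictions), all_cb$test_predictions,
        ci = ci, path = file.path(out_dir, "plot_all_sources.png"))
    }
    write_predictions_csv(baseline$test_predictions, target,
                          file.path(out_dir, "predictions_baseline.csv"))
    plot_estimates(actual_on(target, baseline$test_predictions),
                   baseline$test_predictions,
                   path = file.path(out_dir, "plot_baseline.png"))
    pipe_log(log_path, "run", "complete", sprintf("seed=%d", config$seed))
    list(out_dir = out_dir, phase1 = phase1, phase2 = phase2,
         results = results, baseline = baseline, combos = combos,
         bundle = bundle)
  }, error = function(e) {
    writeLines(sprintf("stage=%s: %s", stage, conditionMessage(e)),
               file.path(out_dir, "FAILED"))
    pipe_log(log_path, stage, "error", conditionMessage(e))
    stop(sprintf("pipeline failed at stage '%s': %s", stage,
                 conditionMessage(e)), call. = FALSE)
  })
  invisible(result)
}

phase1_row <- function(result, target, config) {
  actual <- actual_on(target, result$test_predictions)
  rep <- build_report(actual, result$test_predictions, config$population,
                      smape_convention = config$smape_convention)
  row <- report_row(result$source_name, rep)
  cbind(row[, "label", drop = FALSE],
        data.frame(category = result$category, family = result$family),
        row[, setdiff(names(row), "label")])
}

actual_on <- function(target, predictions) {
  weekly_series(predictions$iso_year, predictions$iso_week,
                ws_value_at(target, predictions$iso_year,
                            predictions$iso_week))
}

write_predictions_csv <- function(predictions, target, path) {
  actual <- ws_value_at(target, predictions$iso_year, predictions$iso_week)
  lines <- c("week,actual,estimate",
             sprintf("%s,%s,%s",
                     week_label(predictions$iso_year, predictions$iso_week),
                     sprintf("%.17g", actual),
                     sprintf("%.17g", predictions$value)))
  writeLines(lines, path)
  invisible(path)
}
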