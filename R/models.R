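#' Phase-1 model zoo
#'
#' Per data stream, a fixed grid of regression models is trained on the
#' lagged-window features and the best candidate is selected on the validation
#' year (by Pearson correlation by default, the metric most aligned with
#' trend surveillance). Families: ordinary least squares, lasso, ridge,
#' elastic net (glmnet), random forest (ranger) and RBF support vector
#' regression (e1071). The historical-fatalities baseline additionally offers
#' an additive Holt-Winters model with period 52.
#'
#' @name base_models
NULL

#' Specification of one model family plus its hyperparameter grid
#'
#' @param family one of `ols`, `lasso`, `ridge`, `elastic_net`,
#'   `random_forest`, `svr`, `holt_winters`
#' @param grid named list mapping hyperparameter names to value vectors; the
#'   full Cartesian product is expanded into candidates
#' @param seed integer seed for stochastic fitters (random forest)
#' @return list of class `model_spec`
#' @export
model_spec <- function(family, grid = list(), seed = 1L) {
  family <- match.arg(family, c("ols", "lasso", "ridge", "elastic_net",
                                "random_forest", "svr", "holt_winters"))
  valid <- switch(family,
    ols = character(), holt_winters = character(),
    lasso = "lambda", ridge = "lambda",
    elastic_net = c("lambda", "alpha"),
    random_forest = c("num_trees", "max_depth"),
    svr = c("cost", "epsilon"))
  if (length(grid) && !all(names(grid) %in% valid)) {
    stop(sprintf("invalid grid keys for family '%s': %s", family,
                 paste(setdiff(names(grid), valid), collapse = ", ")))
  }
  structure(list(family = family, grid = grid, seed = as.integer(seed)),
            class = "model_spec")
}

# deterministic tie-break order: simpler families first
family_order <- c(ols = 1, ridge = 2, lasso = 3, elastic_net = 4, svr = 5,
                  random_forest = 6, holt_winters = 7)

#' Default model zoo (small fixed grids, fully seeded)
#' @param seed seed for stochastic fitters
#' @return list of [model_spec()]
#' @export
default_model_specs <- function(seed = 1L) {
  list(
    model_spec("ols", seed = seed),
    model_spec("lasso", list(lambda = c(0.01, 0.1, 1, 10)), seed = seed),
    model_spec("ridge", list(lambda = c(0.01, 0.1, 1, 10)), seed = seed),
    model_spec("elastic_net", list(lambda = c(0.01, 0.1, 1, 10),
                                   alpha = c(0.25, 0.5, 0.75)), seed = seed),
    model_spec("random_forest", list(num_trees = c(100, 300),
                                     max_depth = c(0, 8)), seed = seed),
    model_spec("svr", list(cost = c(1, 10, 100), epsilon = c(0.1, 1)),
               seed = seed)
  )
}

hyper_label <- function(hyper) {
  if (!length(hyper)) return("")
  paste(sprintf("%s=%g", names(hyper), unlist(hyper)), collapse = ",")
}

fit_one_candidate <- function(family, hyper, X, y, seed) {
  switch(family,
    ols = {
      fit <- stats::lm.fit(cbind(`(Intercept)` = 1, X), y)
      coefs <- fit$coefficients
      coefs[is.na(coefs)] <- 0
      list(kind = "linear", coef = coefs)
    },
    lasso = ,
    ridge = ,
    elastic_net = {
      alpha <- switch(family, lasso = 1, ridge = 0, elastic_net = hyper$alpha)
      # fit along a fixed decreasing path containing the requested penalty so
      # coefficients are reproducible and warm-started consistently
      path <- sort(unique(c(hyper$lambda, 0.01, 0.1, 1, 10, 100)),
                   decreasing = TRUE)
      fit <- glmnet::glmnet(X, y, alpha = alpha, lambda = path,
                            standardize = TRUE)
      list(kind = "glmnet", fit = fit, s = hyper$lambda)
    },
    random_forest = {
      depth <- hyper$max_depth
      fit <- ranger::ranger(
        x = as.data.frame(X), y = y, num.trees = hyper$num_trees,
        max.depth = if (depth > 0) depth else NULL,
        seed = seed, num.threads = 1L)
      list(kind = "ranger", fit = fit)
    },
    svr = {
      fit <- e1071::svm(x = X, y = y, type = "eps-regression",
                        kernel = "radial", cost = hyper$cost,
                        epsilon = hyper$epsilon, scale = TRUE)
      list(kind = "svm", fit = fit)
    },
    stop(sprintf("family '%s' cannot be fitted on a feature matrix", family)))
}

#' Fit every candidate in a list of model specs
#'
#' Each grid point of each spec becomes one candidate. A candidate whose fit
#' errors is flagged `failed` rather than aborting the whole source (one
#' pathological stream must not kill a multi-stream run); if every candidate
#' fails, that is an error.
#'
#' @param train list with `features` (a `feature_matrix`) and `target`
#'   (numeric vector), as produced by [split_by_years()]
#' @param specs list of [model_spec()]
#' @return list of candidate objects (class `nowcast_candidate`)
#' @export
fit_candidates <- function(train, specs) {
  X <- train$features$X
  y <- train$target
  stopifnot(nrow(X) >= 1L, length(y) == nrow(X))
  candidates <- list()
  for (spec in specs) {
    grid <- if (length(spec$grid)) {
      expand.grid(spec$grid, KEEP.OUT.ATTRS = FALSE)
    } else data.frame(row.names = 1L)
    for (g in seq_len(max(nrow(grid), 1L))) {
      hyper <- if (ncol(grid)) as.list(grid[g, , drop = FALSE]) else list()
      fitted <- tryCatch(
        fit_one_candidate(spec$family, hyper, X, y, spec$seed),
        error = function(e) e)
      failed <- inherits(fitted, "error")
      candidates[[length(candidates) + 1L]] <- structure(
        list(family = spec$family, hyper = hyper,
             model = if (!failed) fitted,
             failed = failed,
             message = if (failed) conditionMessage(fitted),
             width = ncol(X), seed = spec$seed),
        class = "nowcast_candidate")
    }
  }
  if (all(vapply(candidates, function(cc) cc$failed, TRUE))) {
    stop("every candidate failed to fit")
  }
  candidates
}

#' Predict weekly values from a fitted candidate
#'
#' @param object a `nowcast_candidate` (or a `source_model_result`, whose
#'   refitted model is used)
#' @param features a `feature_matrix` with the training width
#' @return a [weekly_series()] over the feature matrix's target weeks
#' @export
predict_weekly <- function(object, features) {
  if (inherits(object, "source_model_result")) object <- object$model
  stopifnot(inherits(object, "nowcast_candidate"),
            inherits(features, "feature_matrix"))
  if (object$failed) stop("cannot predict from a failed candidate")
  if (nrow(features$X) == 0L) stop("empty feature matrix")
  if (!is.null(object$width) && ncol(features$X) != object$width) {
    stop(sprintf("width mismatch: model trained on %d features, given %d",
                 object$width, ncol(features$X)))
  }
  X <- features$X
  m <- object$model
  vals <- switch(m$kind,
    linear = as.numeric(cbind(1, X) %*% m$coef),
    glmnet = as.numeric(glmnet::predict.glmnet(m$fit, newx = X, s = m$s)),
    ranger = stats::predict(m$fit, data = as.data.frame(X),
                            num.threads = 1L)$predictions,
    svm = as.numeric(stats::predict(m$fit, newdata = X)),
    holt_winters = hw_lookup(m, features$iso_year, features$iso_week),
    stop("unknown model kind"))
  weekly_series(features$iso_year, features$iso_week, vals)
}

#' Select the best candidate on the validation block
#'
#' Ranks candidates by the criterion on validation predictions: Pearson is
#' maximized, error metrics are minimized. A candidate with undefined Pearson
#' (constant predictions) is ranked last via a -Inf sentinel. Ties break by
#' lower validation RMSE, then by the fixed family order (ols < ridge < lasso
#' < elastic_net < svr < random_forest), then lexicographically on the
#' hyperparameter label — fully deterministic.
#'
#' @param candidates list from [fit_candidates()]
#' @param validation list with `features` and `target` (numeric)
#' @param criterion `pearson`, `rmse`, `mape` or `smape`
#' @return list with `best` (the chosen candidate), `ranking` (data.frame of
#'   scores) and `validation_predictions` (the winner's [weekly_series()])
#' @export
select_best <- function(candidates, validation, criterion = "pearson") {
  criterion <- match.arg(criterion, c("pearson", "rmse", "mape", "smape"))
  fm <- validation$features
  actual <- weekly_series(fm$iso_year, fm$iso_week, validation$target)
  rows <- lapply(seq_along(candidates), function(i) {
    cc <- candidates[[i]]
    if (cc$failed) {
      return(data.frame(i = i, family = cc$family,
                        hyper = hyper_label(cc$hyper), score = -Inf,
                        rmse = Inf, failed = TRUE))
    }
    pred <- predict_weekly(cc, fm)
    r <- tryCatch(pearson(actual, pred), error = function(e) -Inf)
    val_rmse <- rmse(actual, pred)
    score <- switch(criterion,
      pearson = r,
      rmse = -val_rmse,
      mape = -mape(actual, pred),
      smape = -smape(actual, pred))
    data.frame(i = i, family = cc$family, hyper = hyper_label(cc$hyper),
               score = score, rmse = val_rmse, failed = FALSE)
  })
  ranking <- do.call(rbind, rows)
  ord <- order(-ranking$score, ranking$rmse,
               family_order[ranking$family], ranking$hyper)
  ranking <- ranking[ord, , drop = FALSE]
  best <- candidates[[ranking$i[1L]]]
  if (best$failed) stop("no usable candidate (all failed)")
  list(best = best, ranking = ranking,
       validation_predictions = predict_weekly(best, fm))
}

#' Fit, select and refit a phase-1 model for one data stream
#'
#' The end-to-end per-source routine: build lagged features from the stream,
#' split by year, standardize on the training block, fit the zoo, select the
#' best candidate on the validation year, then (by default) refit the chosen
#' family and hyperparameters on train + validation before predicting the test
#' year. Validation predictions always come from the train-only fit, so the
#' downstream stacking ensemble trains on honestly out-of-sample inputs.
#'
#' @param stream a [source_stream()]
#' @param target the [weekly_series()] of true weekly counts
#' @param split a [split_spec()]
#' @param specs list of [model_spec()]
#' @param window,lead sliding-window parameters for this stream
#' @param standardize standardize features on training statistics
#' @param criterion selection metric for [select_best()]
#' @param population rate denominator for validation metrics
#' @param refit refit the winner on train + validation before test prediction
#' @param smape_convention passed through to [build_report()]
#' @return list of class `source_model_result`: `source_name`, `category`,
#'   `family`, `hyper`, `model` (refitted candidate), `validation_metrics`,
#'   `validation_predictions`, `test_predictions`, `ranking`
#' @export
fit_source_model <- function(stream, target, split,
                             specs = default_model_specs(),
                             window = 8L, lead = 0L, standardize = TRUE,
                             criterion = "pearson", population = 325700000,
                             refit = TRUE, smape_convention = "half_sum") {
  stopifnot(inherits(stream, "source_stream"))
  fm <- build_lagged_features(stream$series, window = window, lead = lead,
                              source_name = stream$name)
  blocks <- split_by_years(fm, target, split)
  if (standardize) {
    sc <- standardize_features(blocks$train$features,
                               list(blocks$validation$features,
                                    blocks$test$features))
    train_fm <- sc$train
    val_fm <- sc$others[[1L]]
  } else {
    train_fm <- blocks$train$features
    val_fm <- blocks$validation$features
  }
  candidates <- fit_candidates(list(features = train_fm,
                                    target = blocks$train$target), specs)
  sel <- select_best(candidates,
                     list(features = val_fm,
                          target = blocks$validation$target),
                     criterion = criterion)
  chosen <- sel$best
  # refit the chosen (family, hyperparameters) on train + validation
  if (refit) {
    tv_idx <- seq_len(nrow(blocks$train$features$X) +
                        nrow(blocks$validation$features$X))
    full <- fm_slice(fm, seq_len(nrow(fm$X)))
    tv_fm <- fm_slice(full, tv_idx)
    test_rows <- setdiff(seq_len(nrow(fm$X)), tv_idx)
    test_fm <- fm_slice(full, test_rows)
    tv_y <- c(blocks$train$target, blocks$validation$target)
    if (standardize) {
      sc2 <- standardize_features(tv_fm, list(test_fm))
      tv_fm <- sc2$train
      test_fm <- sc2$others[[1L]]
    }
    refitted <- fit_candidates(
      list(features = tv_fm, target = tv_y),
      list(model_spec_from(chosen)))[[1L]]
    if (refitted$failed) refitted <- chosen  # keep the train-only fit
    model <- refitted
  } else {
    model <- chosen
    test_fm <- if (standardize) sc$others[[2L]] else blocks$test$features
  }
  test_pred <- predict_weekly(model, test_fm)
  val_actual <- weekly_series(val_fm$iso_year, val_fm$iso_week,
                              blocks$validation$target)
  validation_metrics <- build_report(val_actual, sel$validation_predictions,
                                     population,
                                     smape_convention = smape_convention)
  structure(list(source_name = stream$name, category = stream$category,
                 family = chosen$family, hyper = chosen$hyper,
                 model = model,
                 validation_metrics = validation_metrics,
                 validation_predictions = sel$validation_predictions,
                 test_predictions = test_pred,
                 ranking = sel$ranking),
            class = "source_model_result")
}

# single-point spec reproducing a chosen candidate's family + hyperparameters
model_spec_from <- function(candidate) {
  grid <- lapply(candidate$hyper, identity)
  model_spec(candidate$family, grid = grid, seed = candidate$seed)
}

#' @export
print.source_model_result <- function(x, ...) {
  cat(sprintf("<source_model_result> %s: %s(%s), validation r=%.3f\n",
              x$source_name, x$family, hyper_label(x$hyper),
              x$validation_metrics$pearson_r))
  invisible(x)
}
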