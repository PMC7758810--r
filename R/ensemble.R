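#' Phase-2 stacking ensemble
#'
#' The per-source weekly predictions from phase 1 become the input columns of
#' a small feed-forward neural network meta-learner (one hidden layer, linear
#' output), in the spirit of the super learner: the network learns how to
#' weight and combine the streams. It is trained on the validation-year
#' stacked predictions against the validation-year targets — the phase-1
#' models never saw those targets during fitting, so the stacking inputs are
#' honestly out of sample.
#'
#' @name ensemble
NULL

#' Specification of a stacking ensemble
#'
#' @param member_sources character vector of source names, in input-column
#'   order
#' @param hidden_units hidden layer width (default 8, sized for ~52 training
#'   rows)
#' @param activation `"relu"` or `"tanh"`
#' @param epochs full-batch training epochs
#' @param learning_rate Adam step size
#' @param weight_decay L2 penalty on all weights; with ~52 stacking rows the
#'   network must be regularized or it memorizes the validation year
#' @param seed integer seed fixing initialization
#' @param combination_label label for reporting
#' @return list of class `ensemble_spec`
#' @export
ensemble_spec <- function(member_sources, hidden_units = 8L,
                          activation = c("relu", "tanh"), epochs = 2000L,
                          learning_rate = 0.01, weight_decay = 0.3,
                          seed = 1L, combination_label = "ensemble") {
  activation <- match.arg(activation)
  stopifnot(length(member_sources) >= 1L, hidden_units >= 1L, epochs >= 0L,
            learning_rate > 0, weight_decay >= 0)
  structure(list(member_sources = as.character(member_sources),
                 hidden_units = as.integer(hidden_units),
                 activation = activation, epochs = as.integer(epochs),
                 learning_rate = learning_rate, weight_decay = weight_decay,
                 seed = as.integer(seed),
                 combination_label = combination_label),
            class = "ensemble_spec")
}

#' Stack per-source weekly predictions into a feature matrix
#'
#' @param results list of `source_model_result`
#' @param weeks data.frame (`iso_year`, `iso_week`) of requested weeks
#' @param which_predictions `"validation"` or `"test"`
#' @return a `feature_matrix` with one column per member, in `results` order
#' @export
stack_predictions <- function(results, weeks,
                              which_predictions = c("validation", "test")) {
  which_predictions <- match.arg(which_predictions)
  stopifnot(length(results) >= 1L)
  field <- paste0(which_predictions, "_predictions")
  cols <- lapply(results, function(r) {
    pred <- r[[field]]
    pos <- ws_position(pred, weeks$iso_year, weeks$iso_week)
    if (anyNA(pos)) {
      i <- which(is.na(pos))[1L]
      stop(sprintf("member '%s' has no %s prediction for week %s",
                   r$source_name, which_predictions,
                   week_label(weeks$iso_year[i], weeks$iso_week[i])))
    }
    pred$value[pos]
  })
  X <- do.call(cbind, cols)
  colnames(X) <- vapply(results, function(r) r$source_name, "")
  structure(list(X = X, iso_year = as.integer(weeks$iso_year),
                 iso_week = as.integer(weeks$iso_week),
                 source_name = "stacked"),
            class = "feature_matrix")
}

relu <- function(z) pmax(z, 0)
drelu <- function(z) (z > 0) * 1

#' Train the neural-network meta-learner
#'
#' A one-hidden-layer feed-forward network with linear output, trained by
#' full-batch Adam on squared error with L2 weight decay. Inputs and the
#' target are standardized internally (the scalers are stored on the model
#' and inverted at prediction). Deterministic given the spec's seed. The
#' default decay trades a sub-percent shrinkage bias for a large variance
#' reduction — essential when the stacking inputs are one validation year of
#' collinear member predictions.
#'
#' @param stacked_validation `feature_matrix` from [stack_predictions()]
#' @param validation_target [weekly_series()] of true counts on the same weeks
#' @param spec an [ensemble_spec()]
#' @return object of class `ensemble_model`
#' @export
fit_meta_learner <- function(stacked_validation, validation_target, spec) {
  stopifnot(inherits(stacked_validation, "feature_matrix"),
            inherits(spec, "ensemble_spec"))
  X <- stacked_validation$X
  y <- ws_value_at(validation_target, stacked_validation$iso_year,
                   stacked_validation$iso_week)
  n <- nrow(X)
  p <- ncol(X)
  if (n < 2L * spec$hidden_units) {
    stop(sprintf(
      "too few stacking rows (%d) for %d hidden units (need >= %d)",
      n, spec$hidden_units, 2L * spec$hidden_units))
  }
  x_center <- colMeans(X)
  x_scale <- apply(X, 2L, stats::sd)
  x_scale[x_scale <= 0] <- 1
  y_center <- mean(y)
  y_scale <- stats::sd(y)
  if (y_scale <= 0) y_scale <- 1
  Xs <- sweep(sweep(X, 2L, x_center, "-"), 2L, x_scale, "/")
  ys <- (y - y_center) / y_scale
  h <- spec$hidden_units
  act <- switch(spec$activation, relu = relu, tanh = tanh)
  dact <- switch(spec$activation, relu = drelu,
                 tanh = function(z) 1 - tanh(z)^2)
  set.seed(spec$seed)
  W1 <- matrix(stats::rnorm(p * h, 0, sqrt(2 / p)), p, h)
  b1 <- rep(0, h)
  W2 <- matrix(stats::rnorm(h, 0, sqrt(2 / h)), h, 1)
  b2 <- 0
  params <- list(W1 = W1, b1 = b1, W2 = W2, b2 = b2)
  mom <- lapply(params, function(x) x * 0)
  vel <- lapply(params, function(x) x * 0)
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
  for (epoch in seq_len(spec$epochs)) {
    Z1 <- sweep(Xs %*% params$W1, 2L, params$b1, "+")
    A1 <- act(Z1)
    out <- as.numeric(A1 %*% params$W2) + params$b2
    resid <- out - ys
    loss <- mean(resid^2) / 2
    if (!is.finite(loss)) {
      stop(sprintf("non-finite training loss at epoch %d", epoch))
    }
    d_out <- resid / n                        # n x 1
    grads <- list(
      W1 = crossprod(Xs, (d_out %o% as.numeric(params$W2)) * dact(Z1)) +
        spec$weight_decay * params$W1,
      b1 = colSums((d_out %o% as.numeric(params$W2)) * dact(Z1)),
      W2 = crossprod(A1, d_out) + spec$weight_decay * params$W2,
      b2 = sum(d_out))
    for (k in names(params)) {
      mom[[k]] <- beta1 * mom[[k]] + (1 - beta1) * grads[[k]]
      vel[[k]] <- beta2 * vel[[k]] + (1 - beta2) * grads[[k]]^2
      m_hat <- mom[[k]] / (1 - beta1^epoch)
      v_hat <- vel[[k]] / (1 - beta2^epoch)
      params[[k]] <- params[[k]] - spec$learning_rate * m_hat / (sqrt(v_hat) + eps)
    }
  }
  structure(list(spec = spec, params = params,
                 x_center = x_center, x_scale = x_scale,
                 y_center = y_center, y_scale = y_scale,
                 width = p, member_names = colnames(X)),
            class = "ensemble_model")
}

#' Predict weekly estimates from a fitted ensemble
#'
#' @param model an [fit_meta_learner()] result
#' @param stacked `feature_matrix` with the training width
#' @return a [weekly_series()]
#' @export
predict_ensemble <- function(model, stacked) {
  stopifnot(inherits(model, "ensemble_model"),
            inherits(stacked, "feature_matrix"))
  if (ncol(stacked$X) != model$width) {
    stop(sprintf("width mismatch: ensemble trained on %d members, given %d",
                 model$width, ncol(stacked$X)))
  }
  act <- switch(model$spec$activation, relu = relu, tanh = tanh)
  Xs <- sweep(sweep(stacked$X, 2L, model$x_center, "-"), 2L, model$x_scale, "/")
  A1 <- act(sweep(Xs %*% model$params$W1, 2L, model$params$b1, "+"))
  out <- as.numeric(A1 %*% model$params$W2) + model$params$b2
  weekly_series(stacked$iso_year, stacked$iso_week,
                out * model$y_scale + model$y_center)
}

# the six canonical source combinations
combination_members <- function(health, online, baseline_name) {
  list(
    "Health services data sources" = health,
    "Online data sources" = online,
    "Baseline plus health services sources" = c(baseline_name, health),
    "Baseline plus online data sources" = c(baseline_name, online),
    "Health services plus online data sources" = c(health, online),
    "All data sources" = c(baseline_name, health, online)
  )
}

#' Run the six canonical ensemble combinations
#'
#' Builds one stacking ensemble per combination of source categories —
#' health services, online, baseline (historical) and their unions — reusing
#' the same phase-1 predictions for every combination. Economic and
#' meteorological streams are accepted in `results` but are not members of
#' the six canonical combinations (they can be studied via bespoke
#' [ensemble_spec()]s).
#'
#' @param results named list of `source_model_result` for the proxy streams
#' @param baseline the historical-baseline `source_model_result`
#' @param target the true [weekly_series()] (must cover validation and test
#'   weeks)
#' @param population rate denominator
#' @param seed master seed (fanned out per combination)
#' @param labels which combination labels to run (default: all six)
#' @param hidden_units,activation,epochs,learning_rate,weight_decay
#'   meta-learner settings
#' @param smape_convention passed to [build_report()]
#' @return named list of `ensemble_result` (or skip records, for combinations
#'   whose members are missing): each has `spec`, `test_predictions`,
#'   `test_metrics`, `validation_predictions`
#' @export
run_combinations <- function(results, baseline, target,
                             population = 325700000, seed = 1L,
                             labels = NULL, hidden_units = 8L,
                             activation = "relu", epochs = 2000L,
                             learning_rate = 0.01, weight_decay = 0.3,
                             smape_convention = "half_sum") {
  categories <- vapply(results, function(r) r$category, "")
  health <- names(results)[categories == "health_services"]
  online <- names(results)[categories == "online"]
  all_results <- c(results, list(historical = baseline))
  names(all_results)[length(all_results)] <- baseline$source_name
  combos <- combination_members(health, online, baseline$source_name)
  if (!is.null(labels)) {
    unknown <- setdiff(labels, names(combos))
    if (length(unknown)) {
      stop(sprintf("unknown combination label(s): %s",
                   paste(unknown, collapse = ", ")))
    }
    combos <- combos[labels]
  }
  # common prediction calendars across members
  val_pred <- baseline$validation_predictions
  val_weeks <- data.frame(iso_year = val_pred$iso_year,
                          iso_week = val_pred$iso_week)
  test_pred <- baseline$test_predictions
  test_weeks <- data.frame(iso_year = test_pred$iso_year,
                           iso_week = test_pred$iso_week)
  out <- lapply(names(combos), function(label) {
    members <- combos[[label]]
    missing <- setdiff(members, names(all_results))
    if (length(members) == 0L || length(missing)) {
      return(list(label = label, skipped = TRUE,
                  reason = if (length(missing)) {
                    sprintf("missing member source(s): %s",
                            paste(missing, collapse = ", "))
                  } else "no member sources available"))
    }
    member_results <- all_results[members]
    spec <- ensemble_spec(members, hidden_units = hidden_units,
                          activation = activation, epochs = epochs,
                          learning_rate = learning_rate,
                          weight_decay = weight_decay,
                          seed = derive_seed(seed, "ensemble", label),
                          combination_label = label)
    stacked_val <- stack_predictions(member_results, val_weeks, "validation")
    model <- fit_meta_learner(stacked_val, target, spec)
    stacked_test <- stack_predictions(member_results, test_weeks, "test")
    pred <- predict_ensemble(model, stacked_test)
    actual_test <- weekly_series(test_weeks$iso_year, test_weeks$iso_week,
                                 ws_value_at(target, test_weeks$iso_year,
                                             test_weeks$iso_week))
    metrics <- build_report(actual_test, pred, population,
                            smape_convention = smape_convention)
    structure(list(label = label, skipped = FALSE, spec = spec, model = model,
                   test_predictions = pred, test_metrics = metrics,
                   validation_predictions = predict_ensemble(model, stacked_val)),
              class = "ensemble_result")
  })
  names(out) <- names(combos)
  out
}

#' Residual-bootstrap prediction interval for an ensemble
#'
#' Resamples centered validation residuals around the test predictions, B
#' times, and returns pointwise quantile bands (centering means the band
#' always brackets the point estimate; the estimate itself carries whatever
#' bias the ensemble has). The interval method is this package's own
#' convention, recorded in the result.
#'
#' @param result an `ensemble_result`
#' @param target the true [weekly_series()]
#' @param level interval coverage (default 0.95)
#' @param B bootstrap replicates
#' @param seed integer seed
#' @return list with `lower`, `upper` (vectors over test weeks), `level`,
#'   `method = "residual_bootstrap"`
#' @export
ensemble_interval <- function(result, target, level = 0.95, B = 500L,
                              seed = 1L) {
  stopifnot(inherits(result, "ensemble_result"))
  vp <- result$validation_predictions
  va <- ws_value_at(target, vp$iso_year, vp$iso_week)
  res <- vp$value - va
  res <- res - mean(res)
  est <- result$test_predictions$value
  set.seed(as.integer(seed))
  sims <- replicate(B, est - sample(res, length(est), replace = TRUE))
  alpha <- (1 - level) / 2
  list(lower = apply(sims, 1L, stats::quantile, probs = alpha),
       upper = apply(sims, 1L, stats::quantile, probs = 1 - alpha),
       level = level, method = "residual_bootstrap")
}
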