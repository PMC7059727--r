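#' Describe the wrapped prediction model
#'
#' The genetic search is a wrapper feature selector: every candidate
#' statistic combination is scored by the validation performance of a
#' model trained on the selected columns.  The backend is pluggable;
#' random forest (the default) and logistic/linear regression are built
#' in, and any function \code{function(x_train, y_train, x_new)} returning
#' numeric scores can be supplied via \code{fit_fun}.
#'
#' @param task One of \code{"binary"}, \code{"multilabel"},
#'   \code{"regression"}.
#' @param backend \code{"random_forest"}, \code{"logistic_regression"} or
#'   \code{"plugin"}.
#' @param num_trees,max_depth,sample_fraction,mtry Random-forest
#'   hyperparameters (defaults: 100 trees, unlimited depth, bootstrap
#'   sampling, default mtry).  \code{max_depth = 0} means unlimited.
#' @param fit_seed Integer seed fixed for every model fit, so a given
#'   (mask, partition) always yields the same fitness.
#' @param fit_fun Plug-in scorer for \code{backend = "plugin"}.
#' @param regression_fitness_scale Scale on which the GA's regression
#'   fitness (-MSE) is computed: \code{"identity"} (default) or
#'   \code{"log"} for strictly positive, heavy-tailed targets such as
#'   length of stay in hours, where raw-scale MSE differences between
#'   candidate masks drown in fold noise.  Outer-test metrics are always
#'   reported on the identity scale.
#' @return A \code{model_spec}.
#' @export
model_spec <- function(task = c("binary", "multilabel", "regression"),
                       backend = c("random_forest", "logistic_regression",
                                   "plugin"),
                       num_trees = 100L, max_depth = 0L,
                       sample_fraction = 1, mtry = NULL,
                       fit_seed = 1L, fit_fun = NULL,
                       regression_fitness_scale = c("identity", "log")) {
  task <- match.arg(task)
  backend <- match.arg(backend)
  if (backend == "plugin")
    assert_that(is.function(fit_fun), "plugin backend requires fit_fun")
  structure(list(task = task, backend = backend, num_trees = num_trees,
                 max_depth = max_depth, sample_fraction = sample_fraction,
                 mtry = mtry, fit_seed = as.integer(fit_seed),
                 fit_fun = fit_fun,
                 regression_fitness_scale = match.arg(regression_fitness_scale)),
            class = "model_spec")
}

# Fit the backend on (x_train, y_train) and return scores for x_new.
# Binary y: scores are P(y = 1); regression: predicted values;
# multilabel (y matrix): a score matrix, one column per label.
fit_and_score <- function(model, x_train, y_train, x_new) {
  if (model$task == "multilabel") {
    y_train <- as.matrix(y_train)
    return(vapply(seq_len(ncol(y_train)), function(g)
      fit_and_score_single(model, x_train, y_train[, g], x_new),
      numeric(nrow(x_new))))
  }
  fit_and_score_single(model, x_train, y_train, x_new)
}

fit_and_score_single <- function(model, x_train, y_train, x_new) {
  if (model$backend == "plugin")
    return(model$fit_fun(x_train, y_train, x_new))
  classify <- model$task != "regression"
  if (classify && length(unique(y_train)) < 2L)
    return(rep(mean(y_train), nrow(x_new)))
  if (model$backend == "random_forest") {
    y <- if (classify) factor(y_train, levels = c(0, 1)) else y_train
    fit <- ranger::ranger(
      x = x_train, y = y,
      num.trees = model$num_trees,
      max.depth = if (model$max_depth > 0) model$max_depth else NULL,
      sample.fraction = model$sample_fraction,
      mtry = model$mtry,
      probability = classify,
      num.threads = 1L, seed = model$fit_seed,
      verbose = FALSE)
    pr <- predict(fit, data = x_new, num.threads = 1L)$predictions
    if (classify) pr[, "1"] else pr
  } else {  # logistic (classification) / linear (regression) regression
    fam <- if (classify) stats::binomial() else stats::gaussian()
    fit <- suppressWarnings(
      stats::glm.fit(cbind(`(Intercept)` = 1, x_train), y_train,
                     family = fam))
    eta <- drop(cbind(1, x_new) %*% ifelse(is.na(fit$coefficients), 0,
                                           fit$coefficients))
    if (classify) stats::plogis(eta) else eta
  }
}
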