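#' Selection masks over the statistic catalogue
#'
#' A selection mask (the GA's chromosome) is a binary vector with one bit
#' per statistic of the catalogue; bit k selects statistic k across all
#' predictors.
#'
#' @param bits Integer/logical vector of 0/1 values, one per statistic.
#' @param catalog Statistic names giving the bit order.
#' @return Named integer vector of class \code{selection_mask}.
#' @export
#' @examples
#' mask_from_names(c("min", "max", "mean"))
new_selection_mask <- function(bits, catalog = statistic_catalog()) {
  assert_that(length(bits) == length(catalog),
              sprintf("selection mask must have length %d", length(catalog)))
  assert_that(all(bits %in% c(0, 1)), "selection mask bits must be 0/1")
  structure(stats::setNames(as.integer(bits), catalog),
            class = "selection_mask")
}

as_selection_mask <- function(mask, catalog = statistic_catalog()) {
  if (inherits(mask, "selection_mask")) return(mask)
  if (is.character(mask)) return(mask_from_names(mask, catalog))
  new_selection_mask(mask, catalog)
}

#' @rdname new_selection_mask
#' @param names Character vector of selected statistic names.
#' @export
mask_from_names <- function(names, catalog = statistic_catalog()) {
  unknown <- setdiff(names, catalog)
  assert_that(length(unknown) == 0,
              sprintf("unknown statistic(s): %s", paste(unknown, collapse = ", ")))
  new_selection_mask(as.integer(catalog %in% names), catalog)
}

#' @export
print.selection_mask <- function(x, ...) {
  cat(sprintf("<selection_mask> {%s}\n",
              paste(names(x)[x == 1L], collapse = ", ")))
  invisible(x)
}

#' @export
format.selection_mask <- function(x, ...) paste(unclass(x), collapse = "")

#' Genetic-algorithm configuration
#'
#' Defaults follow the published search settings: population of 20 binary
#' chromosomes, single-point crossover with probability 0.6, uniform
#' (per-bit) mutation with probability 0.1, termination when the best
#' fitness fluctuates by less than \code{delta} = 1e-3 over
#' \code{patience_iters} = 50 consecutive iterations or after
#' \code{max_iters} = 200 iterations.  Survivor selection is an elitist
#' (mu + lambda) truncation: parents and offspring are merged and the best
#' \code{population_size} kept, so the best fitness never decreases.
#'
#' @param population_size Number of chromosomes (>= 2).
#' @param crossover_prob,mutation_prob Operator probabilities in [0, 1].
#' @param delta Convergence threshold on the best-fitness fluctuation.
#' @param patience_iters Window length (iterations) of the fluctuation test.
#' @param max_iters Iteration cap.
#' @param rng_seed Integer seed making the whole search reproducible.
#' @return A \code{ga_config}.
#' @export
ga_config <- function(population_size = 20L, crossover_prob = 0.6,
                      mutation_prob = 0.1, delta = 1e-3,
                      patience_iters = 50L, max_iters = 200L,
                      rng_seed = 1L) {
  assert_that(population_size >= 2, "population_size must be >= 2")
  assert_that(crossover_prob >= 0 && crossover_prob <= 1 &&
                mutation_prob >= 0 && mutation_prob <= 1,
              "operator probabilities must lie in [0, 1]")
  assert_that(patience_iters <= max_iters,
              "patience_iters must not exceed max_iters")
  structure(list(population_size = as.integer(population_size),
                 crossover_prob = crossover_prob,
                 mutation_prob = mutation_prob, delta = delta,
                 patience_iters = as.integer(patience_iters),
                 max_iters = as.integer(max_iters),
                 rng_seed = as.integer(rng_seed)),
            class = "ga_config")
}

#' Draw the initial chromosome population
#'
#' Each bit is i.i.d. Bernoulli(0.5); an all-zero draw is repaired by
#' setting one uniformly chosen bit, since an empty statistic set cannot
#' be evaluated.  Uses the current RNG state; seed at the call site (or
#' via \code{\link{ga_select}}) for determinism.
#'
#' @param L Catalogue size.
#' @param config A \code{ga_config}.
#' @param catalog Statistic names (length L).
#' @return List of \code{population_size} selection masks.
#' @export
init_population <- function(L, config, catalog = statistic_catalog()[seq_len(L)]) {
  assert_that(L >= 1, "L must be >= 1")
  lapply(seq_len(config$population_size), function(i) {
    bits <- stats::rbinom(L, 1L, 0.5)
    repair_mask(bits, catalog)
  })
}

repair_mask <- function(bits, catalog) {
  if (sum(bits) == 0L) bits[sample.int(length(bits), 1L)] <- 1L
  new_selection_mask(bits, catalog)
}

#' Validation fitness of a statistic combination
#'
#' Trains the backend on the training rows restricted to the masked
#' columns and scores the validation rows.  Fitness is AUROC for binary
#' tasks, macro-averaged AUROC for multilabel tasks and -MSE for
#' regression, so that higher is always better.  An all-zero mask returns
#' the sentinel 0 (classification) or \code{-Inf} (regression) rather
#' than an error.
#'
#' @param mask Selection mask.
#' @param train,val Lists with elements \code{x} (an imputed
#'   \code{feature_matrix}) and \code{y} (labels: 0/1 vector, 0/1 matrix,
#'   or numeric response).
#' @param model A \code{\link{model_spec}}.
#' @return Scalar fitness.
#' @export
fitness_of <- function(mask, train, val, model) {
  mask <- as_selection_mask(mask)
  if (sum(mask) == 0L)
    return(if (model$task == "regression") -Inf else 0)
  y_tr <- train$y
  y_va <- val$y
  if (model$task == "regression" &&
      identical(model$regression_fitness_scale, "log")) {
    assert_that(all(y_tr > 0) && all(y_va > 0),
                "log fitness scale requires a strictly positive target")
    y_tr <- log(y_tr)
    y_va <- log(y_va)
  }
  xtr <- select_columns(train$x, mask)$values
  xva <- select_columns(val$x, mask)$values
  scores <- fit_and_score(model, xtr, y_tr, xva)
  score_predictions(model$task, scores, y_va)
}

score_predictions <- function(task, scores, y) {
  switch(task,
    binary = metric_auroc(scores, y),
    regression = -metric_mse(scores, y),
    multilabel = {
      y <- as.matrix(y)
      per <- vapply(seq_len(ncol(y)), function(g) {
        if (length(unique(y[, g])) < 2L) NA_real_
        else metric_auroc(scores[, g], y[, g])
      }, 0)
      assert_that(any(is.finite(per)),
                  "no label with both classes present in the validation fold",
                  "icustatsel_fold_error")
      mean(per, na.rm = TRUE)
    })
}

#' Roulette-wheel parent selection
#'
#' Draws \code{n_draws} population indices with replacement, with
#' probability proportional to the supplied non-negative weights.  If all
#' weights are zero a uniform draw is used (with a message), so the search
#' can proceed on degenerate fitness landscapes.
#'
#' @param population List of masks.
#' @param weights Non-negative selection weights (raw AUROC for
#'   classification; within-population ranks for regression, where -MSE is
#'   negative).
#' @param n_draws Number of parents to draw.
#' @return List of drawn masks.
#' @export
roulette_select <- function(population, weights, n_draws) {
  assert_that(length(population) == length(weights) && length(population) > 0,
              "population and weights must be non-empty and equal length")
  assert_that(all(weights >= 0), "roulette weights must be non-negative")
  if (sum(weights) == 0) {
    message("roulette_select: all weights zero; falling back to uniform draw")
    weights <- rep(1, length(population))
  }
  idx <- sample.int(length(population), n_draws, replace = TRUE,
                    prob = weights)
  population[idx]
}

selection_weights <- function(fitnesses, task) {
  if (task == "regression") rank(fitnesses, ties.method = "average")
  else pmax(fitnesses, 0)
}

#' Single-point crossover
#'
#' With probability \code{prob} a cut point in 1..L-1 is drawn uniformly
#' and the suffixes of the two parents are swapped; otherwise the parents
#' are returned unchanged.
#'
#' @param a,b Parent masks of equal length >= 2.
#' @param prob Crossover probability.
#' @return List of two children masks.
#' @export
crossover_single_point <- function(a, b, prob = 0.6) {
  L <- length(a)
  assert_that(length(b) == L && L >= 2, "parents must have equal length >= 2")
  if (stats::runif(1) < prob) {
    cut <- sample.int(L - 1L, 1L)
    tail_a <- a[(cut + 1L):L]
    a[(cut + 1L):L] <- b[(cut + 1L):L]
    b[(cut + 1L):L] <- tail_a
  }
  list(a, b)
}

#' Uniform bit-flip mutation
#'
#' Flips each bit independently with probability \code{prob}; an all-zero
#' result is repaired by setting one uniformly chosen bit.
#'
#' @param mask Selection mask.
#' @param prob Per-bit flip probability.
#' @param catalog Statistic names of the mask.
#' @return The mutated mask.
#' @export
mutate_uniform <- function(mask, prob = 0.1, catalog = names(mask)) {
  flips <- stats::runif(length(mask)) < prob
  bits <- ifelse(flips, 1L - unclass(mask), unclass(mask))
  repair_mask(as.integer(bits), catalog)
}

#' Test the GA termination condition
#'
#' The search stops when the best fitness has fluctuated (max - min) by
#' less than \code{delta} over the last \code{patience_iters} iterations,
#' or when \code{max_iters} iterations have run.
#'
#' @param best_history Numeric vector of per-iteration best fitness.
#' @param config A \code{ga_config}.
#' @return List with logical \code{converged} and \code{reason} in
#'   \code{"converged"}, \code{"max_iters"} or \code{NA}.
#' @export
has_converged <- function(best_history, config) {
  n <- length(best_history)  # element 1 is iteration 0 (initialization)
  assert_that(n >= 1, "best_history must be non-empty")
  iters_run <- n - 1L
  if (iters_run >= config$patience_iters) {
    window <- best_history[(n - config$patience_iters + 1L):n]
    if (max(window) - min(window) < config$delta)
      return(list(converged = TRUE, reason = "converged"))
  }
  if (iters_run >= config$max_iters)
    return(list(converged = TRUE, reason = "max_iters"))
  list(converged = FALSE, reason = NA_character_)
}

#' Genetic-algorithm search for the best statistic combination
#'
#' Runs the binary-encoded genetic search: random initialization,
#' fitness evaluation on the validation partition, roulette-wheel parent
#' selection, single-point crossover, uniform mutation, and elitist
#' (mu + lambda) merge keeping the best \code{population_size} of parents
#' and offspring, until \code{\link{has_converged}}.  Fitness values are
#' cached per mask (a mask's fitness is deterministic given the fixed fit
#' seed), which makes late, near-converged iterations cheap.  The whole
#' search is reproducible from \code{config$rng_seed}.
#'
#' @param train,val Lists with \code{x} (imputed \code{feature_matrix})
#'   and \code{y}; the partitions must be disjoint by patient.
#' @param model A \code{\link{model_spec}}.
#' @param config A \code{\link{ga_config}}.
#' @param catalog Statistic names searched over (restrict to search a
#'   sub-catalogue).
#' @return List with \code{mask} (best-ever mask), \code{fitness} (its
#'   validation fitness), \code{trace} (per-iteration data.frame:
#'   iteration, best_fitness, mean_fitness, best_mask),
#'   \code{termination} reason, \code{n_evaluations} (unique masks
#'   evaluated) and \code{patients_used} (audit: ids of all rows touched).
#' @export
ga_select <- function(train, val, model, config,
                      catalog = unique(train$x$columns$statistic)) {
  overlap <- intersect(rownames(train$x$values), rownames(val$x$values))
  assert_that(length(overlap) == 0,
              "train and validation partitions overlap by patient")
  L <- length(catalog)
  set.seed(config$rng_seed)
  cache <- new.env(parent = emptyenv())
  eval_mask <- function(mask) {
    key <- paste(unclass(mask), collapse = "")
    if (!is.null(cache[[key]])) return(cache[[key]])
    f <- fitness_of(mask, train, val, model)
    cache[[key]] <- f
    f
  }

  pop <- init_population(L, config, catalog)
  fit <- vapply(pop, eval_mask, 0)
  best_idx <- which.max(fit)
  best_mask <- pop[[best_idx]]
  best_fit <- fit[best_idx]
  trace <- list(data.frame(iteration = 0L, best_fitness = best_fit,
                           mean_fitness = mean(fit),
                           best_mask = format(best_mask),
                           stringsAsFactors = FALSE))
  best_history <- best_fit
  iter <- 0L
  repeat {
    state <- has_converged(best_history, config)
    if (state$converged) break
    iter <- iter + 1L
    parents <- roulette_select(pop, selection_weights(fit, model$task),
                               config$population_size)
    offspring <- vector("list", config$population_size)
    for (i in seq(1L, config$population_size, by = 2L)) {
      j <- min(i + 1L, config$population_size)
      kids <- crossover_single_point(parents[[i]], parents[[j]],
                                     config$crossover_prob)
      offspring[[i]] <- kids[[1L]]
      offspring[[j]] <- kids[[2L]]
    }
    offspring <- lapply(offspring, mutate_uniform,
                        prob = config$mutation_prob, catalog = catalog)
    off_fit <- vapply(offspring, eval_mask, 0)
    # elitist (mu + lambda) merge: best population_size of parents + offspring
    merged <- c(pop, offspring)
    merged_fit <- c(fit, off_fit)
    keep <- order(merged_fit, decreasing = TRUE)[seq_len(config$population_size)]
    pop <- merged[keep]
    fit <- merged_fit[keep]
    if (fit[1L] > best_fit) {
      best_fit <- fit[1L]
      best_mask <- pop[[1L]]
    }
    best_history <- c(best_history, best_fit)
    trace[[length(trace) + 1L]] <-
      data.frame(iteration = iter, best_fitness = best_fit,
                 mean_fitness = mean(fit), best_mask = format(best_mask),
                 stringsAsFactors = FALSE)
  }
  assert_that(is.finite(best_fit), "GA finished without any valid evaluation",
              "icustatsel_search_error")
  list(mask = best_mask, fitness = best_fit,
       trace = do.call(rbind, trace), termination = state$reason,
       n_evaluations = length(ls(cache)),
       patients_used = union(rownames(train$x$values),
                             rownames(val$x$values)))
}

#' Write a GA trace as CSV
#' @param ga_result Result of \code{\link{ga_select}}.
#' @param path Output CSV path.
#' @return \code{path}, invisibly.
#' @export
write_ga_trace <- function(ga_result, path) {
  data.table::fwrite(ga_result$trace, path)
  invisible(path)
}
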