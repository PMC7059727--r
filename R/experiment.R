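#' Plan repeated nested cross-validation folds
#'
#' For each of \code{n_repeats} repeats the patients are partitioned into
#' \code{n_outer} outer folds (stratified by outcome for binary tasks, by
#' any-positive for multilabel, unstratified for regression).  Within each
#' outer split the remaining folds are divided into a training block B
#' (\code{n_outer - 2} folds), and a validation fold C chosen uniformly at
#' random (seeded) among them; the held-out fold A is only ever touched by
#' the final outer-test evaluation.  Each repeat re-partitions the cohort
#' under its own derived seed.
#'
#' @param patient_ids Character vector of patient ids.
#' @param labels Outcome used for stratification (0/1 vector or matrix for
#'   multilabel; ignored for regression).
#' @param task \code{"binary"}, \code{"multilabel"} or \code{"regression"}.
#' @param n_outer,n_repeats Fold/repeat counts (defaults 5 and 5).
#' @param base_seed Integer seed; the whole plan is reproducible from it.
#' @return A \code{fold_plan}: list of cells, each with \code{repeat_},
#'   \code{fold}, and id vectors \code{test} (A), \code{train} (B),
#'   \code{val} (C).
#' @export
make_fold_plan <- function(patient_ids, labels = NULL, task = "binary",
                           n_outer = 5L, n_repeats = 5L, base_seed = 1L) {
  n <- length(patient_ids)
  strata <- switch(task,
    binary = {
      assert_that(!is.null(labels), "binary task needs labels to stratify")
      as.integer(labels)
    },
    multilabel = as.integer(rowSums(as.matrix(labels)) > 0),
    regression = rep(0L, n))
  if (task != "regression") {
    tab <- table(strata)
    assert_that(length(tab) == 2 && all(tab >= n_outer),
                sprintf("cannot stratify: need >= %d patients per class", n_outer),
                "icustatsel_planning_error")
  }
  cells <- list()
  for (r in seq_len(n_repeats)) {
    set.seed(mix_seed(base_seed, 101L, r))
    fold_of <- integer(n)
    for (s in unique(strata)) {
      idx <- sample(which(strata == s))
      fold_of[idx] <- rep_len(seq_len(n_outer), length(idx))
    }
    val_choice <- vapply(seq_len(n_outer), function(k)
      sample(setdiff(seq_len(n_outer), k), 1L), 0L)
    for (k in seq_len(n_outer)) {
      cells[[length(cells) + 1L]] <- list(
        repeat_ = r, fold = k,
        test = patient_ids[fold_of == k],
        val = patient_ids[fold_of == val_choice[k]],
        train = patient_ids[!fold_of %in% c(k, val_choice[k])])
    }
  }
  structure(cells, class = "fold_plan",
            n_outer = n_outer, n_repeats = n_repeats, base_seed = base_seed)
}

#' @export
print.fold_plan <- function(x, ...) {
  cat(sprintf("<fold_plan> %d repeats x %d outer folds (%d cells)\n",
              attr(x, "n_repeats"), attr(x, "n_outer"), length(x)))
  invisible(x)
}

extract_task_labels <- function(labels, task,
                                outcome = switch(task,
                                                 regression = "los_hours",
                                                 multilabel = "disease_groups",
                                                 "mortality_hosp")) {
  df <- as.data.frame(labels)
  if (identical(outcome, "disease_groups")) {
    dg <- attr(labels, "disease_groups") %||%
      grep("^dg_\\d+$", names(df), value = TRUE)
    y <- as.matrix(df[, dg, drop = FALSE])
  } else {
    y <- df[[outcome]]
  }
  if (is.matrix(y)) rownames(y) <- df$patient_id else names(y) <- df$patient_id
  y
}

subset_y <- function(y, ids) {
  if (is.matrix(y)) y[ids, , drop = FALSE] else y[ids]
}

subset_fm <- function(fm, ids) subset_patients(fm, ids)

# Shared per-cell evaluation: optional GA on (B, C), refit on B + C, score A.
run_cells <- function(fm, y, task, model, plan, ga = NULL, fixed_mask = NULL,
                      catalog = unique(fm$columns$statistic),
                      impute_scope = c("train_only", "global")) {
  impute_scope <- match.arg(impute_scope)
  results <- list()
  traces <- list()
  for (i in seq_along(plan)) {
    cell <- plan[[i]]
    if (is.null(fixed_mask)) {
      cfg <- ga
      cfg$rng_seed <- mix_seed(ga$rng_seed, cell$repeat_, cell$fold)
      ref <- if (impute_scope == "train_only") cell$train else
        c(cell$train, cell$val)
      fm_inner <- impute_mean(fm, reference_rows = ref)
      sel <- ga_select(
        train = list(x = subset_fm(fm_inner, cell$train),
                     y = subset_y(y, cell$train)),
        val = list(x = subset_fm(fm_inner, cell$val),
                   y = subset_y(y, cell$val)),
        model = model, config = cfg, catalog = catalog)
      # fold-isolation audit: the GA must never have touched fold A
      leaked <- intersect(sel$patients_used, cell$test)
      assert_that(length(leaked) == 0,
                  sprintf("fold-isolation violation: GA touched test patient(s) %s",
                          paste(leaked, collapse = ", ")),
                  "icustatsel_leakage_error")
      mask <- sel$mask
      traces[[i]] <- sel
    } else {
      mask <- as_selection_mask(fixed_mask)
    }
    fit_ids <- c(cell$train, cell$val)
    fm_outer <- impute_mean(fm, reference_rows = fit_ids)
    scores <- fit_and_score(
      model,
      select_columns(subset_fm(fm_outer, fit_ids), mask)$values,
      subset_y(y, fit_ids),
      select_columns(subset_fm(fm_outer, cell$test), mask)$values)
    y_test <- subset_y(y, cell$test)
    met <- outer_metrics(task, scores, y_test)
    results[[i]] <- data.frame(
      repeat_ = cell$repeat_, fold = cell$fold, task = task,
      mask = format(mask), n_selected = sum(mask),
      auroc = met$auroc, auprc = met$auprc, mse = met$mse,
      n_test = length(cell$test), stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, results)
  structure(out, class = c("run_results", "data.frame"),
            traces = traces, catalog = catalog)
}

outer_metrics <- function(task, scores, y_test) {
  if (task == "binary") {
    list(auroc = metric_auroc(scores, y_test),
         auprc = metric_auprc(scores, y_test), mse = NA_real_)
  } else if (task == "multilabel") {
    y_test <- as.matrix(y_test)
    ok <- apply(y_test, 2, function(col) length(unique(col)) == 2)
    assert_that(any(ok), "no label with both classes in the test fold",
                "icustatsel_fold_error")
    list(auroc = mean(vapply(which(ok), function(g)
           metric_auroc(scores[, g], y_test[, g]), 0)),
         auprc = mean(vapply(which(ok), function(g)
           metric_auprc(scores[, g], y_test[, g]), 0)),
         mse = NA_real_)
  } else {
    list(auroc = NA_real_, auprc = NA_real_,
         mse = metric_mse(scores, y_test))
  }
}

#' Nested cross-validation with GA statistic selection
#'
#' The outer loop estimates the generalization of the whole
#' select-then-train procedure: for every (repeat, outer fold) cell the GA
#' searches statistic combinations using only the inner training block B
#' (model fitting) and validation fold C (fitness); the backend is then
#' refit on B + C under the selected mask (imputation means recomputed on
#' B + C) and scored once on the untouched outer test fold A.  A hard
#' audit asserts that no GA fitness evaluation ever saw a test-fold
#' patient.
#'
#' @param fm Feature matrix (post statistic-missingness filter, not yet
#'   imputed; imputation is redone per partition to avoid leakage).
#' @param labels A \code{label_table}.
#' @param task \code{"binary"}, \code{"multilabel"} or \code{"regression"}.
#' @param outcome Label column for binary tasks (default
#'   \code{"mortality_hosp"}); \code{"los_hours"} and the disease-group
#'   columns are implied by the task otherwise.
#' @param model A \code{\link{model_spec}}.
#' @param ga A \code{\link{ga_config}}.
#' @param plan A \code{\link{make_fold_plan}} plan.
#' @param catalog Statistic names searched over.
#' @param impute_scope \code{"train_only"} (default; imputation means from
#'   the training rows only) or \code{"global"}.
#' @return A \code{run_results} data.frame with one row per (repeat,
#'   fold): selected mask, outer-test AUROC/AUPRC/MSE, test size; GA
#'   traces attached as attribute \code{traces}.
#' @export
nested_cv_ga <- function(fm, labels, task, model, ga, plan,
                         outcome = NULL,
                         catalog = unique(fm$columns$statistic),
                         impute_scope = "train_only") {
  y <- if (is.null(outcome)) extract_task_labels(labels, task)
       else extract_task_labels(labels, task, outcome)
  run_cells(fm, y, task, model, plan, ga = ga, catalog = catalog,
            impute_scope = impute_scope)
}

#' Evaluate a fixed statistic combination on the outer folds
#'
#' Same outer folds, refit and scoring as \code{\link{nested_cv_ga}}, but
#' with the mask held fixed (no search); used for the reference
#' combinations such as \{mean\}, \{first\}, \{min, max\},
#' \{min, max, mean\} and \{min, max, mean, std\}.
#'
#' @inheritParams nested_cv_ga
#' @param mask Selection mask, 0/1 vector, or character vector of
#'   statistic names.
#' @return A \code{run_results} data.frame (one row per cell) with a
#'   \code{summary} attribute: mean and standard error per metric.
#' @export
evaluate_fixed_mask <- function(fm, labels, task, model, mask, plan,
                                outcome = NULL) {
  mask <- as_selection_mask(mask)
  assert_that(sum(mask) > 0, "fixed mask must select at least one statistic",
              "icustatsel_empty_selection_error")
  y <- if (is.null(outcome)) extract_task_labels(labels, task)
       else extract_task_labels(labels, task, outcome)
  res <- run_cells(fm, y, task, model, plan, fixed_mask = mask)
  metric <- if (task == "regression") "mse" else "auroc"
  attr(res, "summary") <- lapply(
    c(auroc = "auroc", auprc = "auprc", mse = "mse"), function(mcol) {
      v <- res[[mcol]]
      if (all(is.na(v))) NULL else summarize_metric(v[!is.na(v)])
    })
  res
}

#' Statistic-importance indices over the selected masks
#'
#' For each statistic of the catalogue: \code{Frequency} is the number of
#' result masks containing it (at most repeats x folds), and
#' \code{Mean_AUROC} / \code{Mean_AUPRC} / \code{Mean_MSE} are the
#' unweighted means of the outer-test metrics over exactly those results.
#' A statistic absent from every mask has Frequency 0 and missing means.
#'
#' @param results A \code{run_results} data.frame.
#' @return An \code{importance_table} data.frame with one row per
#'   statistic.
#' @export
importance_table <- function(results) {
  assert_that(nrow(results) > 0, "importance_table needs >= 1 result")
  catalog <- attr(results, "catalog") %||% statistic_catalog()
  bit_mat <- do.call(rbind, lapply(strsplit(results$mask, ""), as.integer))
  colnames(bit_mat) <- catalog
  rows <- lapply(catalog, function(st) {
    sel <- bit_mat[, st] == 1L
    mean_of <- function(mcol) {
      v <- results[[mcol]][sel]
      v <- v[!is.na(v)]
      if (length(v) == 0) NA_real_ else mean(v)
    }
    data.frame(statistic = st, Frequency = sum(sel),
               Mean_AUROC = mean_of("auroc"), Mean_AUPRC = mean_of("auprc"),
               Mean_MSE = mean_of("mse"), stringsAsFactors = FALSE)
  })
  structure(do.call(rbind, rows),
            class = c("importance_table", "data.frame"))
}
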