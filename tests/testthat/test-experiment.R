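test_that("fold plans partition patients with stratification and determinism", {
  set.seed(1)
  ids <- sprintf("p%03d", 1:100)
  y <- setNames(rep(c(1, 0), c(20, 80)), ids)
  plan <- make_fold_plan(ids, y, "binary", base_seed = 7)
  expect_length(plan, 25)
  for (cell in plan) {
    expect_equal(length(cell$test), 20)
    expect_setequal(c(cell$test, cell$train, cell$val), ids)
    expect_length(intersect(cell$test, cell$train), 0)
    expect_length(intersect(cell$test, cell$val), 0)
    expect_length(intersect(cell$train, cell$val), 0)
    expect_equal(length(cell$train), 3 * length(cell$val))
    # stratification: each outer fold holds 20% positives exactly (80/20 split)
    expect_equal(sum(y[cell$test]), 4)
  }
  # outer folds within a repeat partition the cohort
  first_rep <- plan[1:5]
  expect_setequal(unlist(lapply(first_rep, `[[`, "test")), ids)

  plan2 <- make_fold_plan(ids, y, "binary", base_seed = 7)
  expect_identical(plan, plan2)
  plan3 <- make_fold_plan(ids, y, "binary", base_seed = 8)
  expect_false(identical(plan, plan3))

  rare <- setNames(rep(c(1, 0), c(3, 97)), ids)
  expect_error(make_fold_plan(ids, rare, "binary"),
               class = "icustatsel_planning_error")
})

test_that("fixed-mask evaluation matches an independent per-cell oracle", {
  d <- small_synthetic(n = 200, seed = 55)
  fm <- d$fm
  labels <- d$gen$labels
  plan <- make_fold_plan(labels$patient_id, labels$mortality_hosp, "binary",
                         n_outer = 4, n_repeats = 2, base_seed = 12)
  # deterministic plug-in scorer: row mean of the selected columns
  spec <- model_spec("binary", backend = "plugin",
                     fit_fun = function(xtr, ytr, xnew) rowMeans(xnew))
  mask <- mask_from_names(c("mean", "max"))
  res <- evaluate_fixed_mask(fm, labels, "binary", spec, mask, plan)
  expect_equal(nrow(res), 8)

  y <- setNames(labels$mortality_hosp, labels$patient_id)
  for (i in seq_along(plan)) {
    cell <- plan[[i]]
    fit_ids <- c(cell$train, cell$val)
    fmi <- impute_mean(fm, reference_rows = fit_ids)
    x <- select_columns(fmi, mask)$values
    scores <- rowMeans(x[cell$test, , drop = FALSE])
    expect_equal(res$auroc[i], oracle_auroc(scores, y[cell$test]),
                 tolerance = 1e-12)
  }
  s <- attr(res, "summary")
  expect_equal(s$auroc$mean, mean(res$auroc))
  expect_equal(s$auroc$se, sd(res$auroc) / sqrt(8))
})

test_that("a central-signal cohort ranks [mean] above [first]", {
  gen <- generate_cohort(generator_config(
    n_patients = 300, beta_dispersion = 0, beta_shape = 0, seed = 66))
  fm <- filter_statistics_by_missingness(build_feature_matrix(gen$cohort))
  plan <- make_fold_plan(gen$labels$patient_id, gen$labels$mortality_hosp,
                         "binary", n_outer = 5, n_repeats = 1, base_seed = 2)
  model <- eval_model_spec("binary")
  res_mean <- evaluate_fixed_mask(fm, gen$labels, "binary", model, "mean", plan)
  res_first <- evaluate_fixed_mask(fm, gen$labels, "binary", model, "first", plan)
  expect_gt(mean(res_mean$auroc), mean(res_first$auroc))
  res4 <- evaluate_fixed_mask(fm, gen$labels, "binary", model,
                              c("min", "max", "mean", "std"), plan)
  expect_equal(nrow(res4), 5)
  expect_true(all(res4$n_selected == 4))
})

test_that("regression and multilabel tasks run through the same outer loop", {
  d <- small_synthetic(n = 200, seed = 55)
  labels <- d$gen$labels
  plan_r <- make_fold_plan(labels$patient_id, NULL, "regression",
                           n_outer = 4, n_repeats = 1, base_seed = 3)
  res_r <- evaluate_fixed_mask(d$fm, labels, "regression",
                               eval_model_spec("regression"),
                               c("std", "IQR"), plan_r)
  expect_true(all(is.finite(res_r$mse)) && all(res_r$mse > 0))
  expect_true(all(is.na(res_r$auroc)))

  plan_m <- make_fold_plan(labels$patient_id,
                           as.matrix(as.data.frame(labels)[, paste0("dg_", 1:4)]),
                           "multilabel", n_outer = 4, n_repeats = 1,
                           base_seed = 4)
  res_m <- evaluate_fixed_mask(d$fm, labels, "multilabel",
                               eval_model_spec("multilabel"),
                               c("mean", "min", "max"), plan_m)
  expect_true(all(res_m$auroc > 0 & res_m$auroc < 1))
  expect_true(all(res_m$auprc > 0 & res_m$auprc <= 1))
})

test_that("importance table reproduces the hand-enumerated toy example", {
  mk <- function(stats) format(mask_from_names(stats))
  res <- structure(
    data.frame(repeat_ = 1, fold = 1:3, task = "binary",
               mask = c(mk("mean"), mk(c("mean", "std")), mk("std")),
               n_selected = c(1, 2, 1),
               auroc = c(0.7, 0.8, 0.6), auprc = NA_real_, mse = NA_real_,
               n_test = 10, stringsAsFactors = FALSE),
    class = c("run_results", "data.frame"), catalog = statistic_catalog())
  imp <- importance_table(res)
  expect_equal(imp$Frequency[imp$statistic == "mean"], 2)
  expect_equal(imp$Frequency[imp$statistic == "std"], 2)
  expect_equal(imp$Mean_AUROC[imp$statistic == "mean"], 0.75)
  expect_equal(imp$Mean_AUROC[imp$statistic == "std"], 0.70)
  # absent statistic: zero frequency, missing means
  expect_equal(imp$Frequency[imp$statistic == "kurt"], 0)
  expect_true(is.na(imp$Mean_AUROC[imp$statistic == "kurt"]))
  # counting identity: total frequency equals total mask size
  expect_equal(sum(imp$Frequency), sum(res$n_selected))
})
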