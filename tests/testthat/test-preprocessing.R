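mini_cohort <- function(df, ...) new_cohort(df, ...)

test_that("dedupe_and_collapse removes duplicates and collapses timestamps", {
  co <- mini_cohort(data.frame(
    patient_id = "a", predictor = "HR",
    time_h = c(1, 1, 2, 2, 2, 3, 3),
    value = c(5, 5, 3, 5, 100, 4, 6)))
  out <- dedupe_and_collapse(co)
  s <- get_series(out, "a", "HR")
  expect_equal(s$value[s$time_h == 1], 5)        # two identical rows -> one
  expect_equal(s$value[s$time_h == 2], 5)        # median of {3, 5, 100}
  expect_equal(s$value[s$time_h == 3], 5)        # even count: midpoint of {4, 6}
  expect_equal(attr(out, "dedupe_counts")$duplicates_dropped, 1)
  expect_equal(attr(out, "dedupe_counts")$timestamps_collapsed, 2)
})

test_that("outliers require exceeding both the box-plot fence and clinical range", {
  # age-like predictor: cluster in 50..80 with one impossible 300
  vals <- c(seq(50, 80, length.out = 20), 300)
  co <- mini_cohort(data.frame(patient_id = paste0("p", seq_along(vals)),
                               predictor = "age", time_h = 1, value = vals))
  specs <- predictor_specs("age", 0, 120)
  out <- handle_outliers(co, specs)
  expect_equal(unname(out$report$outliers_replaced["age"]), 1)
  med <- median(vals[-21])
  expect_equal(out$cohort$events$value[21], med)

  # outside the fence but inside the clinical range: retained
  vals2 <- c(rep(c(60, 61, 62), 7), 110)
  co2 <- mini_cohort(data.frame(patient_id = paste0("p", seq_along(vals2)),
                                predictor = "age", time_h = 1, value = vals2))
  out2 <- handle_outliers(co2, specs)
  expect_equal(unname(out2$report$outliers_replaced["age"]), 0)
  expect_equal(out2$cohort$events$value, vals2)

  expect_error(handle_outliers(co, predictor_specs("other", 0, 1)),
               class = "icustatsel_config_error")
})

test_that("patient missingness filter uses a strict 30% rule over predictors", {
  preds <- paste0("x", 1:5)
  ev <- rbind(
    data.frame(patient_id = "full", predictor = preds, time_h = 1, value = 1),
    data.frame(patient_id = "miss1", predictor = preds[1:4], time_h = 1, value = 1),
    data.frame(patient_id = "miss2", predictor = preds[1:3], time_h = 1, value = 1))
  co <- mini_cohort(ev, patients = c("full", "miss1", "miss2"),
                    predictors = preds)
  out <- filter_patients_by_missingness(co, threshold = 0.30)
  # miss2 misses 2/5 = 0.40 > 0.30 -> removed; miss1 misses 0.20 -> kept
  expect_setequal(out$cohort$patients, c("full", "miss1"))
  expect_equal(out$report$patients_removed, 1)

  # boundary: exactly 30% missing is retained
  ev10 <- data.frame(patient_id = "p", predictor = paste0("y", 1:7),
                     time_h = 1, value = 1)
  co10 <- mini_cohort(ev10, predictors = paste0("y", 1:10))
  out10 <- filter_patients_by_missingness(co10, threshold = 0.30)
  expect_equal(out10$cohort$patients, "p")
})

test_that("predictor missingness filter uses a strict 40% rule over patients", {
  pats <- paste0("p", 1:10)
  ev <- rbind(
    data.frame(patient_id = pats, predictor = "common", time_h = 1, value = 1),
    data.frame(patient_id = pats[1:5], predictor = "rare", time_h = 1, value = 1),
    data.frame(patient_id = pats[1:7], predictor = "ok", time_h = 1, value = 1),
    data.frame(patient_id = pats[1:6], predictor = "edge", time_h = 1, value = 1))
  co <- mini_cohort(ev, patients = pats,
                    predictors = c("common", "rare", "ok", "edge"))
  out <- filter_predictors_by_missingness(co, threshold = 0.40)
  # rare: 0.50 missing -> removed; ok: 0.30 -> kept; edge: exactly 0.40 -> kept
  expect_setequal(out$cohort$predictors, c("common", "ok", "edge"))

  solo <- mini_cohort(
    data.frame(patient_id = pats[1:2], predictor = "lone", time_h = 1, value = 1),
    patients = pats, predictors = "lone")
  expect_error(filter_predictors_by_missingness(solo, 0.40),
               class = "icustatsel_pipeline_error")
})

test_that("filters are idempotent and only shrink the cohort", {
  set.seed(11)
  gen <- small_synthetic(n = 60, seed = 9)
  co <- inject_missingness(gen$gen$cohort, dropout = 0.25, seed = 2)
  f1 <- filter_patients_by_missingness(co, 0.30)
  f2 <- filter_patients_by_missingness(f1$cohort, 0.30)
  expect_equal(f2$cohort$patients, f1$cohort$patients)
  expect_equal(f2$report$patients_removed, 0)
  expect_lte(length(f1$cohort$patients), length(co$patients))
  g1 <- filter_predictors_by_missingness(f1$cohort, 0.40)
  g2 <- filter_predictors_by_missingness(g1$cohort, 0.40)
  expect_equal(g2$cohort$predictors, g1$cohort$predictors)
})

test_that("the toy fixture cleans exactly as hand-traced", {
  tf <- toy_fixture()
  pp <- preprocess_cohort(tf$cohort, toy_predictor_specs())
  r <- pp$report
  expect_equal(r$duplicates_dropped, 1)
  expect_equal(r$timestamps_collapsed, 1)
  expect_equal(sum(r$outliers_replaced), 1)
  expect_equal(r$patients_removed, 1)
  expect_equal(r$removed_patient_ids, "P8")
  expect_equal(r$predictors_removed, 0)
  expect_equal(r$patients_input, r$patients_removed + r$patients_retained)
  # the 900 bpm artefact is gone, replaced inside the plausible range
  hr <- get_series(pp$cohort, "P4", "HR")
  expect_true(all(hr$value <= 250))
  # P5's same-time Temp pair collapsed to its median
  expect_equal(get_series(pp$cohort, "P5", "Temp")$value[1], 37.2)
})
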