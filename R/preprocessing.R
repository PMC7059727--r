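#' Remove duplicate rows and collapse simultaneous measurements
#'
#' Exact duplicate (patient, predictor, time, value) rows are reduced to
#' one; multiple distinct values charted at the same (patient, predictor,
#' time) are collapsed to their median, so each series has at most one
#' value per timestamp.
#'
#' @param cohort An \code{ehr_cohort}.
#' @return The de-duplicated \code{ehr_cohort}; counts of dropped duplicate
#'   rows and collapsed timestamps are attached as attribute
#'   \code{dedupe_counts}.
#' @export
dedupe_and_collapse <- function(cohort) {
  ev <- cohort$events
  n0 <- nrow(ev)
  ev <- unique(ev, by = c("patient_id", "predictor", "time_h", "value"))
  n1 <- nrow(ev)
  n_multi <- nrow(ev[, .N, by = .(patient_id, predictor, time_h)][N > 1L])
  ev <- ev[, .(value = stats::median(value)),
           by = .(patient_id, predictor, time_h)]
  data.table::setcolorder(ev, c("patient_id", "predictor", "time_h", "value"))
  cohort$events <- ev
  attr(cohort, "dedupe_counts") <-
    list(duplicates_dropped = n0 - n1, timestamps_collapsed = n_multi)
  cohort
}

#' Replace outliers by the cohort median
#'
#' A value is an outlier if and only if it lies outside the per-predictor
#' cohort box-plot fence [Q1 - 1.5 IQR, Q3 + 1.5 IQR] AND outside the
#' predictor's clinical plausibility range; the conjunction protects
#' genuinely extreme but physiologically possible values.  Outliers are
#' replaced by the cohort median of the predictor's retained (non-outlier)
#' values — the classic example is an anonymized age recorded as 300
#' years, replaced by the cohort median age.
#'
#' @param cohort An \code{ehr_cohort}.
#' @param specs A [predictor-spec table][predictor_specs] covering every
#'   predictor present in the cohort.
#' @return List with the corrected \code{cohort} and a
#'   \code{preprocess_report} whose \code{outliers_replaced} is a named
#'   per-predictor count.
#' @export
handle_outliers <- function(cohort, specs) {
  present <- unique(cohort$events$predictor)
  missing_spec <- setdiff(present, specs$predictor)
  assert_that(length(missing_spec) == 0,
              sprintf("no predictor spec for: %s",
                      paste(missing_spec, collapse = ", ")),
              "icustatsel_config_error")
  ev <- data.table::copy(cohort$events)
  replaced <- stats::setNames(integer(length(present)), present)
  for (pred in present) {
    v <- ev[predictor == pred, value]
    qs <- stats::quantile(v, c(0.25, 0.75), names = FALSE, type = 7)
    fence <- c(qs[1] - 1.5 * (qs[2] - qs[1]), qs[2] + 1.5 * (qs[2] - qs[1]))
    sp <- specs[specs$predictor == pred, ]
    is_out <- (v < fence[1] | v > fence[2]) &
      (v < sp$clinical_low | v > sp$clinical_high)
    if (any(is_out)) {
      if (all(is_out)) {
        warning(sprintf("handle_outliers: all values of %s flagged; left unchanged", pred))
        next
      }
      med <- stats::median(v[!is_out])
      ev[predictor == pred, value := replace(value, is_out, med)]
      replaced[pred] <- sum(is_out)
    }
  }
  cohort$events <- ev
  list(cohort = cohort,
       report = new_preprocess_report(outliers_replaced = replaced))
}

#' Remove patients exceeding the predictor-missingness threshold
#'
#' A patient's missing rate is the fraction of the cohort's predictors for
#' which the patient has zero observations inside the window.  Patients
#' with rate strictly greater than \code{threshold} (default 30\%) are
#' removed; boundary-equal rates are retained.
#'
#' @param cohort An \code{ehr_cohort}.
#' @param threshold Missing-rate threshold in (0, 1); default 0.30.
#' @return List with the filtered \code{cohort} and a
#'   \code{preprocess_report}.
#' @export
filter_patients_by_missingness <- function(cohort, threshold = 0.30) {
  assert_that(threshold > 0 && threshold < 1,
              "threshold must be in (0, 1)")
  m <- length(cohort$predictors)
  obs <- unique(cohort$events[, .(patient_id, predictor)])
  n_obs <- obs[, .N, by = patient_id]
  counts <- stats::setNames(rep(0L, length(cohort$patients)), cohort$patients)
  counts[n_obs$patient_id] <- n_obs$N
  # strict rule on the missing count; epsilon guards the boundary against
  # floating-point noise in threshold * m
  drop <- names(counts)[(m - counts) - threshold * m > 1e-9]
  cohort$patients <- setdiff(cohort$patients, drop)
  cohort$events <- cohort$events[patient_id %in% cohort$patients]
  list(cohort = cohort,
       report = new_preprocess_report(patients_removed = length(drop),
                                      patients_retained = length(cohort$patients),
                                      removed_patient_ids = drop))
}

#' Remove predictors exceeding the patient-missingness threshold
#'
#' A predictor's missing rate is the fraction of retained patients with
#' zero observations of it.  Predictors with rate strictly greater than
#' \code{threshold} (default 40\%) are removed.
#'
#' @param cohort An \code{ehr_cohort}.
#' @param threshold Missing-rate threshold in (0, 1); default 0.40.
#' @return List with the filtered \code{cohort} and a
#'   \code{preprocess_report}.
#' @export
filter_predictors_by_missingness <- function(cohort, threshold = 0.40) {
  assert_that(threshold > 0 && threshold < 1,
              "threshold must be in (0, 1)")
  p <- length(cohort$patients)
  obs <- unique(cohort$events[, .(patient_id, predictor)])
  n_obs <- obs[, .N, by = predictor]
  counts <- stats::setNames(rep(0L, length(cohort$predictors)),
                            cohort$predictors)
  counts[n_obs$predictor] <- n_obs$N
  drop <- names(counts)[(p - counts) - threshold * p > 1e-9]
  cohort$predictors <- setdiff(cohort$predictors, drop)
  assert_that(length(cohort$predictors) > 0,
              "all predictors removed by the missingness filter",
              "icustatsel_pipeline_error")
  cohort$events <- cohort$events[predictor %in% cohort$predictors]
  list(cohort = cohort,
       report = new_preprocess_report(predictors_removed = length(drop),
                                      removed_predictors = drop))
}

#' Run the full cleaning cascade
#'
#' Applies, in order: window restriction, de-duplication/interval
#' collapsing, box-plot + clinical-range outlier replacement, the patient
#' missingness filter (against the pre-filter predictor list) and the
#' predictor missingness filter.  The fixed order makes the removal counts
#' reproducible and attributable.
#'
#' @param cohort An \code{ehr_cohort}.
#' @param specs Predictor-spec table for the outlier rule.
#' @param patient_threshold,predictor_threshold Strict missing-rate
#'   thresholds (defaults 0.30 and 0.40).
#' @return List with the cleaned \code{cohort} and a merged
#'   \code{preprocess_report}.
#' @export
preprocess_cohort <- function(cohort, specs,
                              patient_threshold = 0.30,
                              predictor_threshold = 0.40) {
  n_pat0 <- length(cohort$patients)
  cohort <- window_filter(cohort)
  cohort <- dedupe_and_collapse(cohort)
  dd <- attr(cohort, "dedupe_counts")
  out <- handle_outliers(cohort, specs)
  pf <- filter_patients_by_missingness(out$cohort, patient_threshold)
  rf <- filter_predictors_by_missingness(pf$cohort, predictor_threshold)
  report <- new_preprocess_report(
    patients_input = n_pat0,
    duplicates_dropped = dd$duplicates_dropped,
    timestamps_collapsed = dd$timestamps_collapsed,
    outliers_replaced = out$report$outliers_replaced,
    patients_removed = pf$report$patients_removed,
    patients_retained = pf$report$patients_retained,
    removed_patient_ids = pf$report$removed_patient_ids,
    predictors_removed = rf$report$predictors_removed,
    removed_predictors = rf$report$removed_predictors)
  list(cohort = rf$cohort, report = report)
}

new_preprocess_report <- function(...) {
  structure(list(...), class = "preprocess_report")
}

#' @export
print.preprocess_report <- function(x, ...) {
  cat("<preprocess_report>\n")
  for (nm in names(x)) {
    v <- x[[nm]]
    if (length(v) > 6) v <- c(utils::head(v, 6), "...")
    cat(sprintf("  %s: %s\n", nm, paste(v, collapse = ", ")))
  }
  invisible(x)
}

#' Serialize a preprocessing report as JSON
#' @param report A \code{preprocess_report}.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_preprocess_report <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
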