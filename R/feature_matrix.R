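#' Build the patients x (predictor, statistic) feature matrix
#'
#' Summarizes every (patient, predictor) series by the 14-statistic
#' catalogue and assembles the result into one row per patient and one
#' column per (predictor, statistic) pair, named
#' \code{<predictor>__<statistic>}.  Cells of empty series, and statistics
#' undefined at the observed series length, are \code{NA} (missing).
#'
#' @param cohort A preprocessed \code{ehr_cohort}.
#' @param catalog Statistic names to compute (default the full catalogue).
#' @param mode_precision Rounding precision for the mode statistic.
#' @return A \code{feature_matrix}: list with numeric \code{values}
#'   (P x m*L), a \code{columns} map (predictor, statistic per column) and
#'   the patient ids as rownames.
#' @export
build_feature_matrix <- function(cohort, catalog = statistic_catalog(),
                                 mode_precision = 1L) {
  ev <- cohort$events
  data.table::setorder(ev, patient_id, predictor, time_h)
  stats_dt <- ev[, as.list(summarize_series(value, mode_precision)),
                 by = .(patient_id, predictor)]
  patients <- cohort$patients
  predictors <- cohort$predictors
  cols <- data.frame(
    predictor = rep(predictors, each = length(catalog)),
    statistic = rep(catalog, times = length(predictors)),
    stringsAsFactors = FALSE)
  cols$name <- paste0(cols$predictor, "__", cols$statistic)
  values <- matrix(NA_real_, nrow = length(patients), ncol = nrow(cols),
                   dimnames = list(patients, cols$name))
  for (k in seq_along(catalog)) {
    st <- catalog[k]
    wide <- data.table::dcast(stats_dt, patient_id ~ predictor,
                              value.var = st)
    row_idx <- match(wide$patient_id, patients)
    for (pred in intersect(names(wide)[-1], predictors))
      values[row_idx, paste0(pred, "__", st)] <- wide[[pred]]
  }
  new_feature_matrix(values, cols)
}

new_feature_matrix <- function(values, columns, imputed = NULL) {
  structure(list(values = values, columns = columns, imputed = imputed),
            class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("<feature_matrix> %d patients x %d columns (%d predictors x %d statistics), %d missing cells%s\n",
              nrow(x$values), ncol(x$values),
              length(unique(x$columns$predictor)),
              length(unique(x$columns$statistic)),
              sum(is.na(x$values)),
              if (is.null(x$imputed)) "" else
                sprintf(", %d imputed", sum(x$imputed))))
  invisible(x)
}

#' @export
dim.feature_matrix <- function(x) dim(x$values)

#' Drop (predictor, statistic) columns above the missingness threshold
#'
#' Statistics such as std, skew and kurt need a minimal sampling
#' frequency; sparsely charted predictors therefore produce columns that
#' are missing for many patients.  Columns whose missing fraction is
#' strictly greater than \code{threshold} (default 20\%) are removed.
#'
#' @param fm A \code{feature_matrix}.
#' @param threshold Missing-fraction threshold in (0, 1); default 0.20.
#' @return The filtered \code{feature_matrix}; dropped column names are
#'   attached as attribute \code{dropped_columns}.
#' @export
filter_statistics_by_missingness <- function(fm, threshold = 0.20) {
  assert_that(threshold > 0 && threshold < 1, "threshold must be in (0, 1)")
  miss <- colMeans(is.na(fm$values))
  keep <- miss <= threshold + 1e-9   # strict drop rule, boundary retained
  assert_that(any(keep), "all feature columns exceed the missingness threshold",
              "icustatsel_pipeline_error")
  out <- new_feature_matrix(fm$values[, keep, drop = FALSE],
                            fm$columns[keep, , drop = FALSE],
                            if (!is.null(fm$imputed))
                              fm$imputed[, keep, drop = FALSE])
  attr(out, "dropped_columns") <- names(miss)[!keep]
  out
}

#' Mean-impute missing feature cells
#'
#' Each missing cell is replaced by its column mean computed over
#' \code{reference_rows} only; with the default train-only scope the
#' reference is the training partition, so held-out rows are filled with
#' training means and never contribute to them.
#'
#' @param fm A \code{feature_matrix}.
#' @param reference_rows Row names (patient ids) or indices over which the
#'   column means are computed; default all rows.
#' @return The imputed \code{feature_matrix}; \code{imputed} flags mark
#'   filled cells.
#' @export
impute_mean <- function(fm, reference_rows = NULL) {
  v <- fm$values
  ref <- if (is.null(reference_rows)) seq_len(nrow(v)) else reference_rows
  if (is.character(ref)) ref <- match(ref, rownames(v))
  assert_that(!anyNA(ref), "impute_mean: unknown reference rows")
  mu <- colMeans(v[ref, , drop = FALSE], na.rm = TRUE)
  empty <- !is.finite(mu)
  if (any(empty))
    stop_icustatsel(
      sprintf("impute_mean: no observed reference values in column(s): %s",
              paste(colnames(v)[empty], collapse = ", ")),
      "icustatsel_imputation_error")
  miss <- is.na(v)
  v[miss] <- mu[col(v)][miss]
  new_feature_matrix(v, fm$columns, imputed = miss)
}

#' Restrict a feature matrix to the statistics of a selection mask
#'
#' Retains, across every predictor, exactly the columns whose statistic is
#' selected by the mask (bit order = catalogue order).
#'
#' @param fm A \code{feature_matrix}.
#' @param mask A [selection mask][new_selection_mask] or 0/1 vector over
#'   the statistic catalogue.
#' @return The column-restricted \code{feature_matrix}.
#' @export
select_columns <- function(fm, mask) {
  mask <- as_selection_mask(mask)
  selected <- names(mask)[mask == 1L]
  assert_that(sum(mask) > 0, "select_columns: all-zero selection mask",
              "icustatsel_empty_selection_error")
  keep <- fm$columns$statistic %in% selected
  new_feature_matrix(fm$values[, keep, drop = FALSE],
                     fm$columns[keep, , drop = FALSE],
                     if (!is.null(fm$imputed))
                       fm$imputed[, keep, drop = FALSE])
}

#' Restrict a feature matrix to a subset of patients
#'
#' @param fm A \code{feature_matrix}.
#' @param ids Patient ids (rownames) or row indices to keep.
#' @return The row-restricted \code{feature_matrix}.
#' @export
subset_patients <- function(fm, ids) {
  new_feature_matrix(fm$values[ids, , drop = FALSE], fm$columns,
                     if (!is.null(fm$imputed))
                       fm$imputed[ids, , drop = FALSE])
}

#' Write a feature matrix to CSV with a JSON sidecar
#'
#' @param fm A \code{feature_matrix}.
#' @param path Output CSV path; the sidecar is written to
#'   \code{<path>.json} with the dropped-column list and imputed-cell
#'   count.
#' @return \code{path}, invisibly.
#' @export
write_feature_matrix <- function(fm, path) {
  dt <- data.table::data.table(patient_id = rownames(fm$values))
  dt <- cbind(dt, data.table::as.data.table(fm$values))
  data.table::fwrite(dt, path)
  jsonlite::write_json(
    list(dropped_columns = attr(fm, "dropped_columns") %||% character(0),
         imputed_cells = if (is.null(fm$imputed)) 0L else sum(fm$imputed)),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}
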