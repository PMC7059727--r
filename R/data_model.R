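#' Construct an EHR event cohort
#'
#' A cohort bundles a long-format event table (one row per measurement:
#' patient, predictor, time in hours since ICU admission, value) with the
#' patient set, the ordered predictor vocabulary and the analysis-window
#' length.  Patients or predictors without any event are legal members:
#' they are kept here and only removed by the missingness filters, so that
#' every removal is attributable to exactly one pipeline stage.
#'
#' @param events data.frame with columns \code{patient_id},
#'   \code{predictor}, \code{time_h}, \code{value}.
#' @param patients Character vector of patient ids (defaults to the
#'   distinct ids present in \code{events}).
#' @param predictors Ordered character vector of predictor names (defaults
#'   to the distinct names present in \code{events}).
#' @param window_h Analysis window length in hours (default 24).
#' @return Object of class \code{ehr_cohort}.
#' @export
new_cohort <- function(events, patients = NULL, predictors = NULL,
                       window_h = 24) {
  events <- data.table::as.data.table(events)[
    , c("patient_id", "predictor", "time_h", "value")]
  events[, patient_id := as.character(patient_id)]
  events[, predictor := as.character(predictor)]
  events[, time_h := as.numeric(time_h)]
  events[, value := as.numeric(value)]
  patients <- as.character(patients %||% sort(unique(events$patient_id)))
  predictors <- as.character(predictors %||% sort(unique(events$predictor)))
  obj <- structure(list(events = events, patients = patients,
                        predictors = predictors, window_h = window_h),
                   class = "ehr_cohort")
  validate_cohort(obj)
  obj
}

validate_cohort <- function(cohort) {
  ev <- cohort$events
  assert_that(all(ev$patient_id %in% cohort$patients),
              "cohort: events reference unknown patient ids")
  assert_that(all(ev$predictor %in% cohort$predictors),
              "cohort: events reference predictors outside the vocabulary")
  assert_that(all(is.finite(ev$time_h)) && all(ev$time_h >= 0),
              "cohort: time_h must be finite and non-negative")
  assert_that(all(is.finite(ev$value)), "cohort: values must be finite")
  invisible(cohort)
}

#' @export
print.ehr_cohort <- function(x, ...) {
  cat(sprintf("<ehr_cohort> %d patients, %d predictors, %d events, window [0, %g] h\n",
              length(x$patients), length(x$predictors), nrow(x$events),
              x$window_h))
  invisible(x)
}

#' Number of patients / predictors in a cohort
#' @param cohort An \code{ehr_cohort}.
#' @return Integer count.
#' @export
n_patients <- function(cohort) length(cohort$patients)

#' @rdname n_patients
#' @export
n_predictors <- function(cohort) length(cohort$predictors)

#' Retrieve one (patient, predictor) series sorted by time
#'
#' @param cohort An \code{ehr_cohort}.
#' @param patient_id,predictor Identifiers of the series.
#' @return data.frame with columns \code{time_h}, \code{value} ordered by
#'   \code{time_h}; zero rows when the series is empty.
#' @export
get_series <- function(cohort, patient_id, predictor) {
  ev <- cohort$events
  sel <- ev$patient_id == patient_id & ev$predictor == predictor
  s <- ev[sel, c("time_h", "value")]
  data.table::setorder(s, time_h)
  as.data.frame(s)
}

#' Read a long-format event table
#'
#' Reads \code{patient_id,predictor,time_h,value} rows from CSV (or
#' Parquet when the path ends in \code{.parquet} and the arrow package is
#' available).  Rows whose predictor is outside \code{vocabulary} are
#' excluded with a warning; rows with non-finite or unparsable values or
#' times are dropped and counted.  Optional affine unit maps from a
#' [predictor-spec table][read_predictor_specs] are applied at read time
#' when the file carries a \code{unit} column.
#'
#' @param path File path.
#' @param vocabulary Character vector of admissible predictor names.
#' @param specs Optional predictor-spec table providing \code{unit_maps}.
#' @param window_h Analysis window recorded on the cohort (default 24; the
#'   window restriction itself is applied by \code{\link{window_filter}}).
#' @return An \code{ehr_cohort}.  The number of dropped rows is attached as
#'   attribute \code{dropped_rows}.
#' @export
read_events <- function(path, vocabulary, specs = NULL, window_h = 24) {
  assert_that(file.exists(path), sprintf("event file not found: %s", path),
              "icustatsel_io_error")
  dt <- read_table_any(path)
  req <- c("patient_id", "predictor", "time_h", "value")
  missing_cols <- setdiff(req, names(dt))
  assert_that(length(missing_cols) == 0,
              sprintf("event file lacks required column(s): %s",
                      paste(missing_cols, collapse = ", ")),
              "icustatsel_schema_error")
  assert_that(nrow(dt) > 0, "event file contains no rows",
              "icustatsel_empty_cohort_error")
  dt[, time_h := suppressWarnings(as.numeric(time_h))]
  dt[, value := suppressWarnings(as.numeric(value))]

  unknown <- setdiff(unique(dt$predictor), vocabulary)
  if (length(unknown) > 0) {
    warning(sprintf("excluding %d row(s) with predictor(s) outside the vocabulary: %s",
                    sum(dt$predictor %in% unknown),
                    paste(unknown, collapse = ", ")))
    dt <- dt[predictor %in% vocabulary]
  }
  n0 <- nrow(dt)
  dt <- dt[is.finite(value) & is.finite(time_h) & time_h >= 0]
  dropped <- n0 - nrow(dt)
  if (dropped > 0)
    message(sprintf("read_events: dropped %d row(s) with unparsable or negative entries", dropped))
  assert_that(nrow(dt) > 0, "no events remain after parsing",
              "icustatsel_empty_cohort_error")

  if (!is.null(specs) && "unit" %in% names(dt))
    dt <- apply_unit_maps(dt, specs)
  dt <- dt[, c("patient_id", "predictor", "time_h", "value")]
  cohort <- new_cohort(dt, predictors = intersect(vocabulary, unique(dt$predictor)),
                       window_h = window_h)
  attr(cohort, "dropped_rows") <- dropped
  cohort
}

read_table_any <- function(path) {
  if (grepl("\\.parquet$", path)) {
    assert_that(requireNamespace("arrow", quietly = TRUE),
                "reading Parquet requires the arrow package",
                "icustatsel_io_error")
    data.table::as.data.table(arrow::read_parquet(path))
  } else {
    hdr <- names(data.table::fread(path, nrows = 0L))
    cc <- if ("patient_id" %in% hdr) list(character = "patient_id")
    data.table::fread(path, colClasses = cc)
  }
}

apply_unit_maps <- function(dt, specs) {
  maps <- attr(specs, "unit_maps")
  if (is.null(maps)) return(dt)
  for (pred in names(maps)) {
    for (unit in names(maps[[pred]])) {
      m <- maps[[pred]][[unit]]
      sel <- dt$predictor == pred & dt$unit == unit
      dt[sel, value := value * m$scale + m$offset]
    }
  }
  dt
}

#' Write cohort events to CSV
#'
#' @param cohort An \code{ehr_cohort}.
#' @param path Output CSV path.
#' @return \code{path}, invisibly.
#' @export
write_events <- function(cohort, path) {
  data.table::fwrite(cohort$events, path)
  invisible(path)
}

#' Restrict a cohort to its observation window
#'
#' Keeps only events observed in the closed interval [0, window_h] hours
#' after ICU admission.  Patient and predictor sets are unchanged; a
#' patient whose events all fall outside the window keeps an empty series
#' and is handled downstream by the missingness filter.
#'
#' @param cohort An \code{ehr_cohort}.
#' @param window_h Window length in hours (> 0); defaults to the cohort's
#'   recorded window.
#' @return The windowed \code{ehr_cohort}.
#' @export
window_filter <- function(cohort, window_h = cohort$window_h) {
  assert_that(is.numeric(window_h) && length(window_h) == 1 && window_h > 0,
              "window_h must be a positive number")
  cohort$events <- cohort$events[time_h >= 0 & time_h <= window_h]
  cohort$window_h <- window_h
  cohort
}

#' Read a per-patient label table
#'
#' Expects CSV columns \code{patient_id}, \code{mortality_72h},
#' \code{mortality_hosp}, \code{mortality_30d}, \code{mortality_1y},
#' \code{los_hours} and one or more disease-group indicator columns
#' \code{dg_1..dg_G}.  Mortality flags must be monotone over horizons
#' (death within 72 h implies death within 30 days implies death within
#' 1 year); violations are rejected naming the offending patient, never
#' silently repaired.
#'
#' @param path CSV file path.
#' @return A \code{label_table} (data.frame).
#' @export
read_labels <- function(path) {
  assert_that(file.exists(path), sprintf("label file not found: %s", path),
              "icustatsel_io_error")
  dt <- read_table_any(path)
  as_label_table(dt)
}

#' Validate a data.frame of task labels
#'
#' @param df data.frame with the label-table columns (see
#'   \code{\link{read_labels}}).
#' @return The validated \code{label_table}.
#' @export
as_label_table <- function(df) {
  df <- as.data.frame(df)
  req <- c("patient_id", "mortality_72h", "mortality_hosp", "mortality_30d",
           "mortality_1y", "los_hours")
  missing_cols <- setdiff(req, names(df))
  assert_that(length(missing_cols) == 0,
              sprintf("label table lacks column(s): %s",
                      paste(missing_cols, collapse = ", ")),
              "icustatsel_schema_error")
  dg <- grep("^dg_\\d+$", names(df), value = TRUE)
  df$patient_id <- as.character(df$patient_id)
  flags <- c("mortality_72h", "mortality_hosp", "mortality_30d", "mortality_1y")
  for (f in c(flags, dg))
    assert_that(all(df[[f]] %in% c(0, 1)),
                sprintf("label column %s must be binary 0/1", f),
                "icustatsel_validation_error")
  bad <- df$mortality_72h > df$mortality_30d | df$mortality_30d > df$mortality_1y
  if (any(bad))
    stop_icustatsel(
      sprintf("non-monotone mortality flags for patient(s): %s",
              paste(df$patient_id[bad], collapse = ", ")),
      "icustatsel_validation_error")
  assert_that(all(is.finite(df$los_hours)) && all(df$los_hours > 0),
              "los_hours must be positive", "icustatsel_validation_error")
  structure(df, class = c("label_table", "data.frame"),
            disease_groups = dg)
}

#' Write a label table to CSV
#' @param labels A \code{label_table}.
#' @param path Output CSV path.
#' @return \code{path}, invisibly.
#' @export
write_labels <- function(labels, path) {
  data.table::fwrite(as.data.frame(labels), path)
  invisible(path)
}

#' Read predictor specifications from YAML
#'
#' The YAML maps each predictor name to its plausible physiological bounds
#' and optional affine unit conversions, e.g.
#' \preformatted{
#' HR:
#'   clinical_low: 20
#'   clinical_high: 250
#' Temp:
#'   clinical_low: 30
#'   clinical_high: 43
#'   unit_maps:
#'     F: {scale: 0.5556, offset: -17.78}
#' }
#'
#' @param path YAML file path.
#' @return A \code{predictor_spec} data.frame with columns
#'   \code{predictor}, \code{clinical_low}, \code{clinical_high}; unit maps
#'   attached as attribute \code{unit_maps}.
#' @export
read_predictor_specs <- function(path) {
  y <- yaml::read_yaml(path)
  predictor_specs(
    predictor = names(y),
    clinical_low = vapply(y, function(e) as.numeric(e$clinical_low), 0),
    clinical_high = vapply(y, function(e) as.numeric(e$clinical_high), 0),
    unit_maps = Filter(Negate(is.null), lapply(y, `[[`, "unit_maps")))
}

#' Construct a predictor-spec table in code
#'
#' @param predictor Character vector of predictor names.
#' @param clinical_low,clinical_high Numeric physiological bounds,
#'   per predictor, in the predictor's units.
#' @param unit_maps Optional named list of affine unit conversions.
#' @return A \code{predictor_spec} data.frame.
#' @export
predictor_specs <- function(predictor, clinical_low, clinical_high,
                            unit_maps = NULL) {
  assert_that(all(clinical_low < clinical_high),
              "predictor specs: clinical_low must be < clinical_high")
  structure(data.frame(predictor = as.character(predictor),
                       clinical_low = clinical_low,
                       clinical_high = clinical_high,
                       stringsAsFactors = FALSE),
            unit_maps = unit_maps,
            class = c("predictor_spec", "data.frame"))
}
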