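#' Deterministic micro-cohort for unit testing
#'
#' A hand-written 8-patient, 3-predictor (HR, Temp, RR) cohort covering
#' the edge cases of the cleaning cascade:
#' \itemize{
#'   \item an exact duplicate record (P1's first HR row);
#'   \item two Temp values charted at the same timestamp for P5
#'     (collapsed to their median);
#'   \item a constant Temp series (P2) and a length-1 RR series (P3);
#'   \item one HR value of 900 for P4, outside both the box-plot fence
#'     and the clinical range (replaced by the cohort median);
#'   \item one HR event at 30 h for P6 (outside the 24-h window);
#'   \item patient P8 with no RR series at all: missing rate 1/3 > 30\%,
#'     so P8 is the one patient removed.
#' }
#' Hand-traced expectations after \code{\link{preprocess_cohort}} with
#' \code{\link{toy_predictor_specs}()}: 1 duplicate dropped, 1 timestamp
#' collapsed, 1 outlier replaced, 1 patient removed (P8), 0 predictors
#' removed; featurization of the remaining 7 patients gives a 7 x 42
#' matrix before statistic filtering.
#'
#' @return List with \code{cohort} (raw, pre-cleaning) and \code{labels}.
#' @export
toy_fixture <- function() {
  row <- function(p, pred, t, v)
    data.frame(patient_id = p, predictor = pred, time_h = t, value = v,
               stringsAsFactors = FALSE)
  events <- rbind(
    row("P1", "HR", c(1, 1, 3, 5, 7, 9, 11, 13),
        c(80, 80, 82, 85, 90, 88, 84, 81)),          # duplicate at t=1
    row("P1", "Temp", c(2, 8, 14, 20), c(36.8, 37.1, 37.0, 36.9)),
    row("P1", "RR", c(3, 9, 15, 21), c(16, 18, 17, 19)),
    row("P2", "HR", 1:5, c(70, 72, 75, 71, 74)),
    row("P2", "Temp", c(4, 12, 20), c(37, 37, 37)),  # constant series
    row("P2", "RR", c(2, 8, 14, 20), c(14, 15, 16, 15)),
    row("P3", "HR", c(2, 6, 10, 14), c(90, 95, 100, 105)),
    row("P3", "Temp", c(5, 16), c(36.5, 36.9)),
    row("P3", "RR", 7, 22),                          # length-1 series
    row("P4", "HR", c(1, 5, 9, 13, 17), c(88, 92, 900, 95, 91)),  # outlier
    row("P4", "Temp", c(3, 11, 19), c(37.4, 37.8, 38.1)),
    row("P4", "RR", c(2, 9, 16, 23), c(20, 24, 22, 21)),
    row("P5", "HR", c(0.5, 6, 12, 18), c(95, 93, 97, 96)),
    row("P5", "Temp", c(6, 6, 18), c(37.0, 37.4, 37.1)),  # same-time pair
    row("P5", "RR", c(4, 10, 16, 22), c(18, 19, 17, 18)),
    row("P6", "HR", c(2, 8, 14, 20, 30), c(100, 98, 102, 99, 120)),  # t=30
    row("P6", "Temp", c(1, 9, 17), c(36.6, 36.7, 36.8)),
    row("P6", "RR", c(5, 11, 17, 23), c(25, 26, 24, 25)),
    row("P7", "HR", c(3, 9, 15, 21), c(78, 76, 80, 79)),
    row("P7", "Temp", c(2, 10, 18), c(37.2, 37.3, 37.1)),
    row("P7", "RR", c(6, 12, 18, 24), c(15, 14, 16, 15)),
    row("P8", "HR", c(1, 7, 13), c(85, 87, 86)),     # P8 has no RR
    row("P8", "Temp", c(4, 14), c(36.9, 37.0)))
  cohort <- new_cohort(events,
                       patients = paste0("P", 1:8),
                       predictors = c("HR", "Temp", "RR"),
                       window_h = 24)
  labels <- as_label_table(data.frame(
    patient_id = paste0("P", 1:8),
    mortality_72h = c(0, 0, 0, 1, 0, 0, 0, 0),
    mortality_hosp = c(0, 0, 0, 1, 0, 1, 0, 0),
    mortality_30d = c(0, 0, 0, 1, 0, 1, 0, 0),
    mortality_1y = c(0, 1, 0, 1, 0, 1, 0, 0),
    los_hours = c(96, 240, 72, 480, 120, 300, 60, 110),
    dg_1 = c(1, 0, 0, 1, 0, 1, 0, 0),
    dg_2 = c(0, 1, 0, 1, 0, 0, 1, 0),
    dg_3 = c(0, 0, 1, 0, 1, 0, 0, 1),
    dg_4 = c(1, 1, 0, 0, 0, 1, 0, 0),
    stringsAsFactors = FALSE))
  list(cohort = cohort, labels = labels)
}

#' Clinical-range specs for the toy fixture's predictors
#' @return A \code{predictor_spec} table for HR, Temp, RR.
#' @export
toy_predictor_specs <- function() {
  predictor_specs(predictor = c("HR", "Temp", "RR"),
                  clinical_low = c(20, 30, 5),
                  clinical_high = c(250, 43, 60))
}
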