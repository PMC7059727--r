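#' Area under the ROC curve
#'
#' Computed by the rank (Mann-Whitney) formula, which equals the
#' probability that a random positive is scored above a random negative,
#' with half credit for ties.
#'
#' @param scores Numeric prediction scores.
#' @param labels Binary 0/1 labels of the same length; both classes must
#'   be present.
#' @return AUROC in [0, 1].
#' @export
#' @examples
#' metric_auroc(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1))  # 0.75
metric_auroc <- function(scores, labels) {
  assert_that(length(scores) == length(labels),
              "scores and labels must have equal length")
  labels <- as.integer(labels)
  n_pos <- sum(labels == 1L)
  n_neg <- sum(labels == 0L)
  assert_that(n_pos > 0 && n_neg > 0,
              "AUROC undefined: both classes must be present",
              "icustatsel_metric_error")
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1L]) - n_pos * (n_pos + 1) / 2) /
    (as.numeric(n_pos) * n_neg)
}

#' Area under the precision-recall curve (average precision)
#'
#' Area under the precision-recall step curve by the average-precision
#' summation: thresholds sweep the distinct score values in decreasing
#' order and each recall increment is weighted by the precision at that
#' threshold, so tied scores enter as a single threshold.
#'
#' @param scores Numeric prediction scores.
#' @param labels Binary 0/1 labels; at least one positive required.
#' @return AUPRC in (0, 1]; the chance level equals the prevalence.
#' @export
metric_auprc <- function(scores, labels) {
  assert_that(length(scores) == length(labels),
              "scores and labels must have equal length")
  labels <- as.integer(labels)
  n_pos <- sum(labels == 1L)
  assert_that(n_pos > 0, "AUPRC undefined: no positive labels",
              "icustatsel_metric_error")
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  y <- labels[ord]
  tp <- cumsum(y)
  pp <- seq_along(y)
  last_of_threshold <- c(s[-1] != s[-length(s)], TRUE)
  tp <- tp[last_of_threshold]
  pp <- pp[last_of_threshold]
  recall <- tp / n_pos
  precision <- tp / pp
  sum(diff(c(0, recall)) * precision)
}

#' Mean squared error
#'
#' @param predictions,truths Numeric vectors of equal length >= 1.
#' @return Mean of squared residuals.
#' @export
metric_mse <- function(predictions, truths) {
  assert_that(length(predictions) == length(truths) && length(truths) >= 1,
              "predictions and truths must have equal positive length")
  mean((predictions - truths)^2)
}

#' Mean and standard error of a metric vector
#'
#' @param values Numeric vector of per-fold metric values (length >= 2).
#' @return List with \code{mean} and \code{se} (sample standard deviation
#'   over sqrt(n)).
#' @export
summarize_metric <- function(values) {
  assert_that(length(values) >= 2,
              "summarize_metric needs at least 2 values",
              "icustatsel_summary_error")
  list(mean = mean(values), se = stats::sd(values) / sqrt(length(values)))
}
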