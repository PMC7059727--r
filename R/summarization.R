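#' The 14-statistic summary catalogue
#'
#' Ordered names of the summary statistics used to featurize each
#' (patient, predictor) series.  The catalogue covers the three families of
#' distribution descriptors used throughout the package: central tendency
#' (\code{mean}, \code{median}, \code{Q1}, \code{Q3}, \code{mode},
#' \code{first}), dispersion (\code{min}, \code{max}, \code{range},
#' \code{std}, \code{CV}, \code{IQR}) and distribution shape (\code{skew},
#' \code{kurt}).
#'
#' @return Character vector of length 14 (the catalogue order is the bit
#'   order of every [selection mask][new_selection_mask]).
#' @export
#' @examples
#' statistic_catalog()
statistic_catalog <- function() {
  c("min", "max", "range", "mean", "std", "CV", "median",
    "Q1", "Q3", "IQR", "mode", "skew", "kurt", "first")
}

#' Statistic families of the catalogue
#'
#' @return Named list with character vectors \code{central},
#'   \code{dispersion} and \code{shape} partitioning
#'   \code{\link{statistic_catalog}()}.
#' @export
statistic_families <- function() {
  list(central    = c("mean", "median", "Q1", "Q3", "mode", "first"),
       dispersion = c("min", "max", "range", "std", "CV", "IQR"),
       shape      = c("skew", "kurt"))
}

#' Summarize a univariate series by the 14-statistic catalogue
#'
#' Computes the full summary-statistic vector of a time-ordered numeric
#' series.  Statistics that are undefined at the observed series length are
#' returned as \code{NA} (missing), never as 0: \code{std} and \code{CV}
#' require n >= 2, \code{skew} n >= 3 and \code{kurt} n >= 4.  A
#' zero-variance series has \code{skew} and \code{kurt} missing and
#' \code{CV} = 0.  \code{CV} is also missing when the mean is numerically
#' zero (|mean| < 1e-12).  An empty series yields all 14 entries missing.
#'
#' Conventions: quantiles (\code{median}, \code{Q1}, \code{Q3}) use linear
#' interpolation between order statistics (type 7); \code{std} is the
#' sample standard deviation (denominator n - 1); \code{skew} and
#' \code{kurt} are the bias-corrected sample skewness and bias-corrected
#' excess kurtosis; \code{mode} is the most frequent value after rounding
#' to \code{mode_precision} decimals, ties broken by the smallest value;
#' \code{first} is the earliest observation.
#'
#' @param values Numeric vector, ordered by observation time.
#' @param mode_precision Number of decimals the recording device resolves;
#'   values are rounded to this precision before the mode count (default 1).
#' @return Named numeric vector of length 14 in catalogue order, with
#'   \code{NA} marking undefined entries.
#' @export
#' @examples
#' summarize_series(c(1, 2, 3, 4, 5))
#' summarize_series(c(7, 7, 7))   # zero variance: skew/kurt missing, CV 0
#' summarize_series(numeric(0))   # all missing
summarize_series <- function(values, mode_precision = 1L) {
  out <- stats::setNames(rep(NA_real_, 14L), statistic_catalog())
  n <- length(values)
  if (n == 0L) return(out)
  assert_that(all(is.finite(values)), "summarize_series: values must be finite")

  out[["min"]]    <- min(values)
  out[["max"]]    <- max(values)
  out[["range"]]  <- out[["max"]] - out[["min"]]
  mu              <- mean(values)
  out[["mean"]]   <- mu
  qs              <- stats::quantile(values, c(0.25, 0.5, 0.75),
                                     names = FALSE, type = 7)
  out[["Q1"]]     <- qs[1L]
  out[["median"]] <- qs[2L]
  out[["Q3"]]     <- qs[3L]
  out[["IQR"]]    <- qs[3L] - qs[1L]
  out[["first"]]  <- values[1L]

  r <- round(values, mode_precision)
  tab <- table(r)
  out[["mode"]] <- min(as.numeric(names(tab)[tab == max(tab)]))

  if (n >= 2L) {
    s <- stats::sd(values)
    out[["std"]] <- s
    out[["CV"]] <- if (s == 0) 0 else if (abs(mu) < 1e-12) NA_real_ else s / mu
    m2 <- sum((values - mu)^2) / n
    if (m2 > 0) {
      if (n >= 3L) {
        g1 <- (sum((values - mu)^3) / n) / m2^1.5
        out[["skew"]] <- g1 * sqrt(n * (n - 1)) / (n - 2)
      }
      if (n >= 4L) {
        g2 <- (sum((values - mu)^4) / n) / m2^2 - 3
        out[["kurt"]] <- ((n + 1) * g2 + 6) * (n - 1) / ((n - 2) * (n - 3))
      }
    }
  }
  out
}
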