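# Independent brute-force oracles used to validate the implementation.
# These deliberately avoid the code paths of the package: quantiles are
# interpolated from an explicit sort, moments come from direct power sums,
# AUROC from a double loop over positive-negative pairs, AUPRC from an
# explicit step-curve sweep.

# linear-interpolation (type 7) quantile from a hand-rolled sort
oracle_quantile <- function(x, p) {
  s <- sort(x)
  n <- length(s)
  h <- (n - 1) * p + 1
  lo <- floor(h)
  hi <- ceiling(h)
  s[lo] + (h - lo) * (s[hi] - s[lo])
}

oracle_summarize <- function(x, mode_precision = 1L) {
  out <- setNames(rep(NA_real_, 14), statistic_catalog())
  n <- length(x)
  if (n == 0) return(out)
  s <- sort(x)
  out["min"] <- s[1]; out["max"] <- s[n]; out["range"] <- s[n] - s[1]
  mu <- sum(x) / n
  out["mean"] <- mu
  out["Q1"] <- oracle_quantile(x, 0.25)
  out["median"] <- oracle_quantile(x, 0.5)
  out["Q3"] <- oracle_quantile(x, 0.75)
  out["IQR"] <- out["Q3"] - out["Q1"]
  out["first"] <- x[1]
  r <- round(x, mode_precision)
  counts <- vapply(unique(r), function(v) sum(r == v), 0)
  out["mode"] <- min(unique(r)[counts == max(counts)])
  if (n >= 2) {
    m2 <- sum((x - mu)^2) / n
    sd2 <- sum((x - mu)^2) / (n - 1)
    out["std"] <- sqrt(sd2)
    out["CV"] <- if (out["std"] == 0) 0 else
      if (abs(mu) < 1e-12) NA_real_ else out["std"] / mu
    if (m2 > 0) {
      if (n >= 3) {
        g1 <- (sum((x - mu)^3) / n) / m2^1.5
        out["skew"] <- g1 * sqrt(n * (n - 1)) / (n - 2)
      }
      if (n >= 4) {
        g2 <- (sum((x - mu)^4) / n) / m2^2 - 3
        out["kurt"] <- ((n + 1) * g2 + 6) * (n - 1) / ((n - 2) * (n - 3))
      }
    }
  }
  out
}

# AUROC as the concordant-pair count with half credit for ties
oracle_auroc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  total <- 0
  for (p in pos) for (q in neg)
    total <- total + (p > q) + 0.5 * (p == q)
  total / (length(pos) * length(neg))
}

# AUPRC as the explicit precision-recall step curve over distinct thresholds
oracle_auprc <- function(scores, labels) {
  thr <- sort(unique(scores), decreasing = TRUE)
  n_pos <- sum(labels == 1)
  area <- 0
  prev_recall <- 0
  for (t in thr) {
    called <- scores >= t
    precision <- sum(labels[called] == 1) / sum(called)
    recall <- sum(labels[called] == 1) / n_pos
    area <- area + (recall - prev_recall) * precision
    prev_recall <- recall
  }
  area
}

# random series of mixed integer/real values, lengths 1..max_len
random_series <- function(max_len = 200) {
  n <- sample.int(max_len, 1)
  if (runif(1) < 0.3) round(rnorm(n, 50, 20)) else rnorm(n, 50, 20)
}
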