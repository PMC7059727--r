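#' Configuration of the synthetic EHR cohort generator
#'
#' The generator emulates the shape of a critical-care event table:
#' per-predictor observation counts are Poisson within a 24-hour window,
#' observation times are uniform, and values follow a (centered)
#' skew-normal whose location, scale and shape are driven by three
#' patient-level latent severity factors — a mean-shift factor z, a
#' variance-inflation factor d and a skewness factor s.  Task labels are
#' generated from the same latents: mortality by a logistic model with
#' horizon-wise increasing prevalence, length of stay log-normal in the
#' dispersion factor, disease groups Bernoulli with group-specific
#' loadings.  Because the statistic families pick up exactly these factors
#' (central statistics recover z, dispersion statistics d, shape
#' statistics s), the informative families are known by construction and
#' recoverable by the pipeline.
#'
#' Default predictors are a five-signal vitals panel (HR, SBP, RR, Temp,
#' SpO2) with textbook adult means/scales and charting rates between 8 and
#' 20 observations per 24 h.  Default effect sizes are strong
#' (\code{beta_central} = \code{beta_dispersion} = 2.5,
#' \code{beta_shape} = 1.5): the generator's purpose is planted,
#' recoverable signal, and a slope of 2.5 on a standard-normal latent
#' puts the Bayes AUROC near 0.9.
#'
#' @param n_patients Number of patients (>= 20; default 2000).
#' @param predictors data.frame with columns \code{predictor}, \code{mu}
#'   (baseline mean), \code{sigma} (baseline scale), \code{lambda}
#'   (expected observations per window), \code{loading_central} (a_j:
#'   location shift per unit z), \code{loading_dispersion} (c_j:
#'   log-scale inflation per unit d), \code{loading_shape} (alpha_j:
#'   skew-normal shape per unit s).
#' @param window_h Observation window in hours (default 24).
#' @param beta_central,beta_dispersion,beta_shape Mortality-model
#'   coefficients on z, d, s.
#' @param prevalence Named target prevalences for \code{mortality_72h},
#'   \code{mortality_hosp}, \code{mortality_30d}, \code{mortality_1y};
#'   must be strictly inside (0, 1) and monotone over the 72h/30d/1y
#'   horizons.
#' @param los_gamma0 Intercept of the log-LOS model (default
#'   \code{log(112.8)}, i.e. a median stay of 4.7 days).
#' @param los_gamma_dispersion Slope of log-LOS on the dispersion factor d.
#' @param los_sigma Residual standard deviation of log-LOS.
#' @param n_groups Number of disease groups G (default 20).
#' @param group_loading Scale of the group-specific loadings on z.
#' @param dropout Per-(patient, predictor) probability that the whole
#'   series is unobserved (default 0; see
#'   \code{\link{inject_missingness}}).
#' @param seed Master seed; each patient draws from an independently
#'   derived substream, so enlarging \code{n_patients} leaves existing
#'   patients' event series unchanged.
#' @return A \code{generator_config}.
#' @export
generator_config <- function(n_patients = 2000L,
                             predictors = default_predictor_panel(),
                             window_h = 24,
                             beta_central = 2.5, beta_dispersion = 2.5,
                             beta_shape = 1.5,
                             prevalence = c(mortality_72h = 0.08,
                                            mortality_hosp = 0.195,
                                            mortality_30d = 0.25,
                                            mortality_1y = 0.35),
                             los_gamma0 = log(112.8),
                             los_gamma_dispersion = 0.5,
                             los_sigma = 0.4,
                             n_groups = 20L, group_loading = 1.0,
                             dropout = 0, seed = 1L) {
  assert_that(n_patients >= 20, "n_patients must be >= 20")
  assert_that(all(predictors$lambda > 0) && all(predictors$sigma > 0),
              "predictor rates and scales must be positive")
  assert_that(all(prevalence > 0 & prevalence < 1),
              "configured prevalences imply degenerate labels",
              "icustatsel_generator_error")
  horizons <- c("mortality_72h", "mortality_30d", "mortality_1y")
  assert_that(!is.unsorted(prevalence[horizons]),
              "prevalence must be monotone over 72h <= 30d <= 1y")
  assert_that(dropout >= 0 && dropout <= 1, "dropout must be in [0, 1]")
  structure(list(n_patients = as.integer(n_patients),
                 predictors = predictors, window_h = window_h,
                 beta_central = beta_central,
                 beta_dispersion = beta_dispersion,
                 beta_shape = beta_shape, prevalence = prevalence,
                 los_gamma0 = los_gamma0,
                 los_gamma_dispersion = los_gamma_dispersion,
                 los_sigma = los_sigma, n_groups = as.integer(n_groups),
                 group_loading = group_loading, dropout = dropout,
                 seed = as.integer(seed)),
            class = "generator_config")
}

#' Default five-signal vitals panel of the generator
#' @return data.frame of per-predictor generator parameters.
#' @export
default_predictor_panel <- function() {
  data.frame(
    predictor = c("HR", "SBP", "RR", "Temp", "SpO2"),
    mu = c(85, 120, 19, 37, 96.5),
    sigma = c(15, 18, 5, 0.7, 2.5),
    lambda = c(20, 18, 16, 8, 14),
    loading_central = c(9, 10.8, 3, 0.42, 1.5),    # 0.6 * sigma
    loading_dispersion = rep(0.35, 5),
    loading_shape = rep(3, 5),
    stringsAsFactors = FALSE)
}

# Standard skew-normal deviates (location 0, scale 1, shape alpha),
# centered to mean zero.
rskewnorm_centered <- function(n, alpha) {
  delta <- alpha / sqrt(1 + alpha^2)
  u0 <- stats::rnorm(n)
  u1 <- stats::rnorm(n)
  x <- delta * abs(u0) + sqrt(1 - delta^2) * u1
  x - delta * sqrt(2 / pi)
}

#' Generate a synthetic cohort with known statistic-level signal
#'
#' Draws per-patient latent factors z, d, s ~ N(0, 1); for each
#' (patient, predictor) a Poisson(\code{lambda_j}) number of events at
#' uniform times in the window, with values from a centered skew-normal
#' with location \code{mu_j + a_j z}, scale \code{sigma_j exp(c_j d)} and
#' shape \code{alpha_j s}.  Mortality labels share one uniform draw per
#' patient compared against horizon-wise increasing logistic
#' probabilities, which enforces the monotone flag invariant by
#' construction; horizon intercepts are solved against the realized
#' cohort so empirical prevalence matches the configured targets.
#' Length of stay is log-normal in d; disease groups are Bernoulli with
#' group-specific loadings on z.  Fully deterministic given the master
#' seed.
#'
#' @param config A \code{\link{generator_config}}.
#' @return List with \code{cohort} (an \code{ehr_cohort}),
#'   \code{labels} (a \code{label_table}) and \code{ground_truth}
#'   (informative statistic families per task plus the per-patient
#'   latents).
#' @export
generate_cohort <- function(config) {
  np <- config$n_patients
  preds <- config$predictors
  ids <- sprintf("P%05d", seq_len(np))
  lat <- matrix(0, np, 5,
                dimnames = list(ids, c("z", "d", "s", "u_mort", "eps_los")))
  events <- vector("list", np)
  for (i in seq_len(np)) {
    set.seed(mix_seed(config$seed, 1L, i))
    lat[i, "z"] <- stats::rnorm(1)
    lat[i, "d"] <- stats::rnorm(1)
    lat[i, "s"] <- stats::rnorm(1)
    lat[i, "u_mort"] <- stats::runif(1)
    lat[i, "eps_los"] <- stats::rnorm(1)
    ev_i <- vector("list", nrow(preds))
    for (j in seq_len(nrow(preds))) {
      n_ij <- stats::rpois(1, preds$lambda[j])
      if (n_ij == 0) next
      times <- sort(stats::runif(n_ij, 0, config$window_h))
      loc <- preds$mu[j] + preds$loading_central[j] * lat[i, "z"]
      scl <- preds$sigma[j] * exp(preds$loading_dispersion[j] * lat[i, "d"])
      shp <- preds$loading_shape[j] * lat[i, "s"]
      ev_i[[j]] <- data.table::data.table(
        patient_id = ids[i], predictor = preds$predictor[j],
        time_h = times,
        value = loc + scl * rskewnorm_centered(n_ij, shp))
    }
    events[[i]] <- data.table::rbindlist(ev_i)
  }
  events <- data.table::rbindlist(events)
  cohort <- new_cohort(events, patients = ids,
                       predictors = preds$predictor,
                       window_h = config$window_h)
  if (config$dropout > 0)
    cohort <- inject_missingness(cohort, config$dropout,
                                 seed = mix_seed(config$seed, 3L))

  eta <- config$beta_central * lat[, "z"] +
    config$beta_dispersion * lat[, "d"] +
    config$beta_shape * lat[, "s"]
  p_of <- function(target) {
    b0 <- stats::uniroot(function(b) mean(stats::plogis(b + eta)) - target,
                         c(-40, 40))$root
    stats::plogis(b0 + eta)
  }
  prev <- config$prevalence
  u <- lat[, "u_mort"]
  labels <- data.frame(
    patient_id = ids,
    mortality_72h = as.integer(u < p_of(prev[["mortality_72h"]])),
    mortality_hosp = as.integer(u < p_of(prev[["mortality_hosp"]])),
    mortality_30d = as.integer(u < p_of(prev[["mortality_30d"]])),
    mortality_1y = as.integer(u < p_of(prev[["mortality_1y"]])),
    los_hours = exp(config$los_gamma0 +
                      config$los_gamma_dispersion * lat[, "d"] +
                      config$los_sigma * lat[, "eps_los"]),
    stringsAsFactors = FALSE)
  # disease groups: group g loads on z with a deterministic multiplier
  g_mult <- 0.4 + 0.8 * (seq_len(config$n_groups) - 1) /
    max(1, config$n_groups - 1)
  g_prev <- seq(0.10, 0.40, length.out = config$n_groups)
  for (g in seq_len(config$n_groups)) {
    eta_g <- config$group_loading * g_mult[g] * lat[, "z"]
    b0 <- stats::uniroot(function(b) mean(stats::plogis(b + eta_g)) - g_prev[g],
                         c(-40, 40))$root
    set.seed(mix_seed(config$seed, 4L, g))
    labels[[paste0("dg_", g)]] <-
      as.integer(stats::runif(np) < stats::plogis(b0 + eta_g))
  }
  fam <- statistic_families()
  informative <- list(
    mortality = c(if (config$beta_central != 0) fam$central,
                  if (config$beta_dispersion != 0) fam$dispersion,
                  if (config$beta_shape != 0) fam$shape),
    los = if (config$los_gamma_dispersion != 0) fam$dispersion else character(0),
    disease_groups = if (config$group_loading != 0) fam$central else character(0))
  list(cohort = cohort, labels = as_label_table(labels),
       ground_truth = list(informative = informative,
                           latent = data.frame(patient_id = ids,
                                               z = lat[, "z"], d = lat[, "d"],
                                               s = lat[, "s"],
                                               row.names = NULL)))
}

#' Remove whole (patient, predictor) series at random
#'
#' Emulates unmeasured predictors: with the given probability all events
#' of a (patient, predictor) pair are dropped, producing the missingness
#' the patient/predictor filters are designed to handle.
#'
#' @param cohort An \code{ehr_cohort}.
#' @param dropout Scalar or per-predictor named vector of dropout
#'   probabilities in [0, 1].
#' @param seed Integer seed.
#' @return The thinned \code{ehr_cohort}.
#' @export
inject_missingness <- function(cohort, dropout, seed = 1L) {
  assert_that(all(dropout >= 0 & dropout <= 1),
              "dropout probabilities must lie in [0, 1]")
  pairs <- data.table::CJ(patient_id = cohort$patients,
                          predictor = cohort$predictors)
  p <- if (length(dropout) == 1L) rep(dropout, nrow(pairs))
       else dropout[pairs$predictor]
  set.seed(seed)
  pairs <- pairs[stats::runif(nrow(pairs)) < p]
  if (nrow(pairs) > 0) {
    drop_key <- paste(pairs$patient_id, pairs$predictor)
    ev_key <- paste(cohort$events$patient_id, cohort$events$predictor)
    cohort$events <- cohort$events[!ev_key %in% drop_key]
  }
  cohort
}

#' Write a generated cohort to disk
#'
#' Emits the event and label CSVs in the package's standard schemas plus a
#' \code{ground_truth.json} documenting the informative families.
#'
#' @param generated Result of \code{\link{generate_cohort}}.
#' @param dir Output directory (created if absent).
#' @return \code{dir}, invisibly.
#' @export
write_cohort <- function(generated, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_events(generated$cohort, file.path(dir, "events.csv"))
  write_labels(generated$labels, file.path(dir, "labels.csv"))
  jsonlite::write_json(generated$ground_truth$informative,
                       file.path(dir, "ground_truth.json"),
                       auto_unbox = FALSE, digits = NA)
  invisible(dir)
}
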