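# Shared evaluation-scale settings for the synthetic studies run by the
# test suite: paper-scale operator settings (population 20, crossover 0.6,
# mutation 0.1, delta 1e-3) with a reduced iteration budget, and a light
# random-forest fitness backend.  The package defaults keep the full-scale
# settings.

eval_ga_config <- function(rng_seed = 1L, ...) {
  ga_config(population_size = 20L, crossover_prob = 0.6,
            mutation_prob = 0.1, delta = 1e-3,
            patience_iters = 6L, max_iters = 12L, rng_seed = rng_seed, ...)
}

eval_model_spec <- function(task = "binary", ...) {
  model_spec(task, backend = "random_forest", num_trees = 30L,
             max_depth = 8L, sample_fraction = 0.5,
             regression_fitness_scale = if (task == "regression") "log"
             else "identity", ...)
}

# small cohort reused across GA/experiment tests (built once per run)
small_cohort_cache <- new.env()
small_synthetic <- function(n = 300, seed = 42, ...) {
  key <- paste(n, seed, ...)
  if (is.null(small_cohort_cache[[key]])) {
    gen <- generate_cohort(generator_config(n_patients = n, seed = seed, ...))
    fm <- filter_statistics_by_missingness(build_feature_matrix(gen$cohort))
    small_cohort_cache[[key]] <- list(gen = gen, fm = fm)
  }
  small_cohort_cache[[key]]
}
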