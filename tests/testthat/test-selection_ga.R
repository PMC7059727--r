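test_that("masks are validated and constructible from statistic names", {
  m <- mask_from_names(c("min", "max", "mean"))
  expect_s3_class(m, "selection_mask")
  expect_equal(sum(m), 3)
  expect_equal(format(m), "11010000000000")
  expect_error(new_selection_mask(rep(1, 5)), class = "icustatsel_argument_error")
  expect_error(mask_from_names("nope"), class = "icustatsel_argument_error")
})

test_that("initial populations have the right shape, determinism and repair", {
  cfg <- ga_config(rng_seed = 5)
  set.seed(5)
  pop <- init_population(14, cfg)
  expect_length(pop, 20)
  expect_true(all(vapply(pop, length, 0L) == 14))
  expect_true(all(vapply(pop, sum, 0L) >= 1))
  set.seed(5)
  pop2 <- init_population(14, cfg)
  expect_identical(pop, pop2)
  # the repair rule leaves exactly one bit set on an all-zero draw
  set.seed(1)
  repaired <- icustatsel:::repair_mask(rep(0L, 14), statistic_catalog())
  expect_equal(sum(repaired), 1)
})

test_that("roulette selection draws in proportion to the weights", {
  pop <- lapply(1:3, function(i) new_selection_mask(
    as.integer(seq_len(14) == i)))
  set.seed(42)
  draws <- roulette_select(pop, c(0.2, 0.3, 0.5), 100000)
  freq <- table(vapply(draws, format, ""))
  ord <- vapply(pop, format, "")
  p_hat <- as.numeric(freq[ord]) / 100000
  se <- sqrt(c(0.2, 0.3, 0.5) * c(0.8, 0.7, 0.5) / 100000)
  expect_true(all(abs(p_hat - c(0.2, 0.3, 0.5)) < 3 * se))

  sure <- roulette_select(pop, c(0, 1, 0), 50)
  expect_true(all(vapply(sure, format, "") == format(pop[[2]])))
  expect_message(roulette_select(pop, c(0, 0, 0), 10), "uniform")
})

test_that("single-point crossover swaps suffixes and respects its probability", {
  a <- new_selection_mask(c(1, 1, 0, 0, 1, 1, rep(0, 8)))
  b <- new_selection_mask(c(0, 0, 1, 1, 0, 0, rep(0, 8)))
  # find a seed whose cut lands after position 2 to check the exact swap
  cut_seed <- NULL
  for (sd in 1:200) {
    set.seed(sd)
    runif(1)                       # the operator's trigger draw
    if (sample.int(13, 1) == 2) { cut_seed <- sd; break }
  }
  set.seed(cut_seed)
  kids <- crossover_single_point(a, b, prob = 1)
  expect_equal(unname(unclass(kids[[1]])[1:6]), c(1, 1, 1, 1, 0, 0))
  expect_equal(unname(unclass(kids[[2]])[1:6]), c(0, 0, 0, 0, 1, 1))

  none <- crossover_single_point(a, b, prob = 0)
  expect_identical(none[[1]], a)
  expect_identical(none[[2]], b)
  same <- crossover_single_point(a, a, prob = 1)
  expect_identical(same[[1]], a)
})

test_that("uniform mutation flips bits at the configured rate", {
  m <- new_selection_mask(rep(c(1L, 0L), 7))
  expect_identical(mutate_uniform(m, prob = 0), m)
  flipped <- mutate_uniform(m, prob = 1)
  expect_equal(unclass(flipped), 1L - unclass(m), ignore_attr = TRUE)

  set.seed(9)
  n_flips <- 0
  n_trials <- 20000
  for (i in seq_len(n_trials)) {
    mut <- mutate_uniform(m, prob = 0.1)
    n_flips <- n_flips + sum(unclass(mut) != unclass(m))
  }
  rate <- n_flips / (n_trials * 14)
  se <- sqrt(0.1 * 0.9 / (n_trials * 14))
  expect_lt(abs(rate - 0.1), 3 * se + 1e-4)  # repair adds a tiny upward bias
})

test_that("convergence combines fitness stagnation with the iteration cap", {
  cfg <- ga_config(delta = 1e-3, patience_iters = 50, max_iters = 200)
  flat <- rep(0.8, 51)           # constant across 50 iterations
  expect_true(has_converged(flat, cfg)$converged)
  expect_equal(has_converged(flat, cfg)$reason, "converged")
  wiggle <- 0.5 + cumsum(runif(201, 0, 2e-3))  # keeps fluctuating
  out <- has_converged(wiggle, cfg)
  expect_true(out$converged)
  expect_equal(out$reason, "max_iters")
  young <- seq(0.5, 0.6, length.out = 31)
  expect_false(has_converged(young, cfg)$converged)
})

test_that("fitness handles sentinels, perfect separation and noise correctly", {
  d <- small_synthetic(n = 120, seed = 21)
  fm <- impute_mean(d$fm)
  y <- setNames(d$gen$labels$mortality_hosp, d$gen$labels$patient_id)
  ids <- rownames(fm$values)
  tr <- ids[1:80]; va <- ids[81:120]
  train <- list(x = icustatsel:::subset_fm(fm, tr), y = y[tr])
  val <- list(x = icustatsel:::subset_fm(fm, va), y = y[va])

  model <- eval_model_spec("binary")
  expect_equal(fitness_of(rep(0, 14), train, val, model), 0)
  expect_equal(fitness_of(rep(0, 14), train, val,
                          eval_model_spec("regression")), -Inf)

  # a feature equal to the label separates perfectly -> fitness 1
  perfect <- fm
  perfect$values[, "HR__mean"] <- y[ids]
  ptrain <- list(x = icustatsel:::subset_fm(perfect, tr), y = y[tr])
  pval <- list(x = icustatsel:::subset_fm(perfect, va), y = y[va])
  spec <- model_spec("binary", backend = "plugin",
                     fit_fun = function(xtr, ytr, xnew) xnew[, "HR__mean"])
  expect_equal(fitness_of(mask_from_names("mean"), ptrain, pval, spec), 1)

  # pure-noise scores sit at chance level
  set.seed(2)
  y_big <- rbinom(2000, 1, 0.3)
  expect_lt(abs(metric_auroc(rnorm(2000), y_big) - 0.5), 0.05)
})

test_that("the elitist GA is deterministic, monotone and invariant without operators", {
  d <- small_synthetic(n = 150, seed = 33)
  fm <- impute_mean(d$fm)
  y <- setNames(d$gen$labels$mortality_hosp, d$gen$labels$patient_id)
  ids <- rownames(fm$values)
  tr <- ids[1:100]; va <- ids[101:150]
  train <- list(x = icustatsel:::subset_fm(fm, tr), y = y[tr])
  val <- list(x = icustatsel:::subset_fm(fm, va), y = y[va])
  model <- eval_model_spec("binary")

  cfg <- eval_ga_config(rng_seed = 4)
  r1 <- ga_select(train, val, model, cfg)
  r2 <- ga_select(train, val, model, cfg)
  expect_identical(r1$mask, r2$mask)
  expect_identical(r1$trace, r2$trace)
  expect_true(all(diff(r1$trace$best_fitness) >= 0))
  expect_equal(r1$fitness, max(r1$trace$best_fitness))

  frozen <- ga_config(population_size = 6, crossover_prob = 0,
                      mutation_prob = 0, patience_iters = 3, max_iters = 5,
                      rng_seed = 8)
  rf <- ga_select(train, val, model, frozen)
  # without operators the population cannot move: best fitness is flat
  expect_equal(length(unique(rf$trace$best_fitness)), 1)

  expect_error(ga_select(train, list(x = train$x, y = train$y), model, cfg),
               class = "icustatsel_argument_error")
})

test_that("the GA beats random search at an equal evaluation budget", {
  d <- small_synthetic(n = 200, seed = 71)
  fm <- impute_mean(d$fm)
  y <- setNames(d$gen$labels$mortality_hosp, d$gen$labels$patient_id)
  ids <- rownames(fm$values)
  tr <- ids[1:130]; va <- ids[131:200]
  train <- list(x = subset_patients(fm, tr), y = y[tr])
  val <- list(x = subset_patients(fm, va), y = y[va])
  model <- eval_model_spec("binary")

  wins <- 0
  for (s in 1:5) {
    res <- ga_select(train, val, model, eval_ga_config(rng_seed = 700 + s))
    set.seed(900 + s)
    random_best <- max(vapply(seq_len(res$n_evaluations), function(i) {
      bits <- rbinom(14, 1, 0.5)
      if (sum(bits) == 0) bits[sample.int(14, 1)] <- 1
      fitness_of(new_selection_mask(bits), train, val, model)
    }, 0))
    if (res$fitness >= random_best) wins <- wins + 1
  }
  expect_gte(wins, 4)
})
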