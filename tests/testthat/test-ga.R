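test_that("population initialization respects the non-empty invariant", {
  withr::with_seed(1, {
    pop1 <- init_population(1, 20)
    expect_true(all(pop1 == 1))
  })
  p1 <- withr::with_seed(2, init_population(50, 30))
  p2 <- withr::with_seed(2, init_population(50, 30))
  expect_identical(p1, p2)
  expect_true(all(rowSums(p1) >= 1))
  # mean bits per chromosome ~ Binomial(100, 0.5): within 5 sigma of 50
  big <- withr::with_seed(3, init_population(100, 50))
  expect_lt(abs(mean(rowSums(big)) - 50), 5 * 5 / sqrt(50))
})

test_that("SUS selection follows the ranking wheel", {
  # two individuals with expectations 2:0 -> the best is selected twice,
  # regardless of its position
  withr::with_seed(1, {
    expect_equal(sort(select_parents(c(0.2, 0.9), 2)), c(1, 1))
    expect_equal(sort(select_parents(c(0.9, 0.2), 2)), c(2, 2))
  })
  # equal fitnesses: counts within 1 of the uniform share
  counts <- withr::with_seed(4, table(select_parents(rep(1, 10), 20)))
  expect_true(all(abs(counts - 2) <= 1))
  # reproducible for a fixed RNG state
  a <- withr::with_seed(5, select_parents(runif(8), 6))
  b <- withr::with_seed(5, select_parents(runif(8), 6))
  expect_identical(a, b)
})

test_that("double-point crossover swaps the inner segment and conserves bits", {
  a <- c(1L, 1L, 1L, 1L, 1L, 1L)
  b <- c(0L, 0L, 0L, 0L, 0L, 0L)
  ch <- double_point_crossover(a, b, prob = 1, cuts = c(2, 4))
  expect_equal(ch[[1]], c(1L, 1L, 0L, 0L, 1L, 1L))
  expect_equal(ch[[2]], c(0L, 0L, 1L, 1L, 0L, 0L))
  # prob = 0: identical copies
  ch0 <- double_point_crossover(a, b, prob = 0)
  expect_equal(ch0[[1]], a)
  # bit conservation when no repair triggers
  withr::with_seed(2, {
    for (i in 1:20) {
      x <- sample(0:1, 12, replace = TRUE); x[1] <- 1L
      y <- sample(0:1, 12, replace = TRUE); y[12] <- 1L
      ch <- double_point_crossover(x, y, prob = 1)
      if (any(ch[[1]] == 1) && any(ch[[2]] == 1))
        expect_equal(sum(ch[[1]]) + sum(ch[[2]]), sum(x) + sum(y))
    }
  })
  expect_error(double_point_crossover(a, b[1:3]), "length mismatch")
})

test_that("mutation flips at the configured rate with all-zero repair", {
  m <- c(0L, 1L, 1L, 0L)
  expect_equal(withr::with_seed(1, mutate_mask(m, 0)), m)
  expect_equal(withr::with_seed(1, mutate_mask(m, 1)), c(1L, 0L, 0L, 1L))
  # all-ones flipped entirely -> repaired to a single set bit
  repaired <- withr::with_seed(1, mutate_mask(c(1L, 1L), 1))
  expect_equal(sum(repaired), 1)
  # empirical flip rate ~ 0.7 per chromosome of length 100
  flips <- withr::with_seed(6, {
    replicate(400, sum(mutate_mask(rep(1L, 100), 0.007) == 0))
  })
  expect_lt(abs(mean(flips) - 0.7), 5 * sqrt(0.7 * 0.993) / sqrt(400))
})

test_that("elitist reinsertion keeps the best and never regresses", {
  old <- rbind(rep(1L, 4), rep(c(1L, 0L), 2), rep(0:1, 2))
  old_fit <- c(0.1, 0.5, 0.9)
  off <- rbind(c(1L, 1L, 0L, 0L), c(0L, 0L, 1L, 1L))
  # best old individual beats all offspring -> survives
  res <- reinsert(old, old_fit, off, c(0.3, 0.4))
  expect_true(any(apply(res$pop, 1, identical, old[1, ])))
  expect_lte(min(res$fit), min(old_fit))
  # all offspring better -> new population is offspring + best old
  res2 <- reinsert(old, old_fit, off, c(0.01, 0.02))
  expect_equal(sort(res2$fit), sort(c(0.1, 0.01, 0.02)))
  expect_error(reinsert(old, old_fit, rbind(off, off), rep(0, 4)), "offspring")
})

test_that("fitness is a deterministic, memoized function of the mask", {
  d <- small_signal_dataset(n = 60, p = 10, n_inf = 3, seed = 7)$dataset
  mask <- rep(1L, 10)
  f1 <- ga_fitness(mask, d, rf_ntree = 60, ga_seed = 5)
  f2 <- ga_fitness(mask, d, rf_ntree = 60, ga_seed = 5)
  expect_identical(f1, f2)
  cache <- new.env()
  f3 <- ga_fitness(mask, d, rf_ntree = 60, ga_seed = 5, cache = cache)
  expect_identical(f3, ga_fitness(mask, d, rf_ntree = 60, ga_seed = 5,
                                  cache = cache))
  # full mask equals a plain forest with the same derived seed policy
  tr <- d$split == "train"
  direct <- fit_forest(d$X[tr, ], d$y[tr], ntree = 60,
                       seed = garf:::mask_seed(mask, 5))
  expect_identical(f1, oob_mse(direct))
  expect_error(ga_fitness(rep(0L, 10), d), "empty")
})

test_that("informative masks beat noise masks of equal size", {
  wins <- 0
  for (s in 1:5) {
    g <- generate_qsar(synth_spec(n_compounds = 100, n_descriptors = 20,
                                  n_informative = 5, noise_sd = 0.8,
                                  seed = s))
    d <- qsar_dataset(g$dataset$X, g$dataset$y, rep("train", 100))
    inf_mask <- as.integer(g$truth$role == "informative")
    noise_cols <- which(g$truth$role == "noise")[1:5]
    noise_mask <- integer(20); noise_mask[noise_cols] <- 1L
    f_inf <- ga_fitness(inf_mask, d, rf_ntree = 100, ga_seed = s)
    f_noise <- ga_fitness(noise_mask, d, rf_ntree = 100, ga_seed = s)
    wins <- wins + (f_inf < f_noise)
  }
  expect_gte(wins, 4)
})

test_that("the GA run is monotone, reproducible, and improves on random init", {
  d <- small_signal_dataset(n = 70, p = 16, n_inf = 4, seed = 11)$dataset
  cfg <- ga_config(population_size = 12, max_generations = 6,
                   rf_ntree = 50, ga_seed = 13)
  res1 <- run_ga(d, cfg)
  res2 <- run_ga(d, cfg)
  expect_identical(res1$best_mask, res2$best_mask)
  expect_identical(res1$history, res2$history)
  expect_true(all(diff(res1$history$best) <= 0))
  expect_equal(res1$best_fitness, min(res1$history$best))
  expect_true(any(res1$best_mask == 1))
  expect_gte(res1$cache_hits, 0)
})
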