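test_that("default mtry is one third of the descriptor count", {
  expect_equal(default_mtry(40), 13)
  expect_equal(default_mtry(108), 36)
  expect_equal(default_mtry(2), 1)
})

test_that("forest fitting is seeded, guarded, and constant-y-stable", {
  x <- random_matrix(40, 6, seed = 1)
  y <- withr::with_seed(1, rnorm(40))
  m1 <- fit_forest(x, y, ntree = 50, seed = 3)
  m2 <- fit_forest(x, y, ntree = 50, seed = 3)
  expect_identical(m1$oob, m2$oob)
  expect_identical(predict(m1, x), predict(m2, x))

  expect_error(fit_forest(x, y, mtry = 7), "mtry")
  expect_error(fit_forest(x[1, , drop = FALSE], y[1]), "at least 2")

  yc <- rep(4.2, 40)
  mc <- fit_forest(x, yc, ntree = 50, seed = 1)
  expect_true(all(abs(predict(mc, x) - 4.2) < 1e-12))
  expect_true(is.na(oob_r2(mc)))  # degenerate, reported missing not error
})

test_that("OOB machinery flags never-out-of-bag samples and bounds error", {
  x <- random_matrix(30, 5, seed = 2)
  y <- withr::with_seed(2, rnorm(30))
  # with very few trees some samples are in-bag everywhere
  m_small <- fit_forest(x, y, ntree = 2, seed = 1)
  if (any(m_small$oob_missing)) expect_error(oob_mse(m_small), "out-of-bag")
  m <- fit_forest(x, y, ntree = 200, seed = 1)
  expect_false(any(m$oob_missing))
  expect_gte(oob_mse(m), 0)
  # permuted labels: OOB MSE approaches the label variance (no-signal limit)
  d <- small_signal_dataset(n = 150, p = 10, n_inf = 3, seed = 5)$dataset
  y_perm <- withr::with_seed(7, sample(d$y))
  mp <- fit_forest(d$X, y_perm, ntree = 300, seed = 2)
  v <- mean((y_perm - mean(y_perm))^2)
  expect_lt(abs(oob_mse(mp) - v) / v, 0.25)
})

test_that("importance separates signal from noise and zeros unused columns", {
  sd_ <- small_signal_dataset(n = 120, p = 12, n_inf = 4, seed = 4)
  X <- cbind(sd_$dataset$X, DCONST = rep(1, 120))
  m <- fit_forest(X, sd_$dataset$y, ntree = 300, seed = 6)
  imp <- variable_importance(m)
  expect_equal(imp$inc_node_purity[imp$descriptor == "DCONST"], 0)
  inf <- sd_$truth$descriptor[sd_$truth$role == "informative"]
  noise <- sd_$truth$descriptor[sd_$truth$role == "noise"]
  expect_gt(mean(imp$inc_mse_pct[imp$descriptor %in% inf]),
            mean(imp$inc_mse_pct[imp$descriptor %in% noise]))
})

test_that("forest is column-order invariant after canonicalization", {
  d <- small_signal_dataset(seed = 9)$dataset
  shuf <- withr::with_seed(9, sample(ncol(d$X)))
  x_shuffled <- d$X[, shuf]
  canon <- function(x) x[, order(colnames(x))]
  m1 <- fit_forest(canon(d$X), d$y, ntree = 50, seed = 2)
  m2 <- fit_forest(canon(x_shuffled), d$y, ntree = 50, seed = 2)
  expect_identical(m1$oob, m2$oob)
})

test_that("mtry sweep reports reproducible medians and guards degeneracy", {
  d <- small_signal_dataset(n = 60, p = 8, n_inf = 3, seed = 2)$dataset
  s1 <- mtry_sweep(d$X, d$y, c(1, 3), replications = 2, ntree = 60, seed = 5)
  s2 <- mtry_sweep(d$X, d$y, c(1, 3), replications = 2, ntree = 60, seed = 5)
  expect_identical(s1$medians, s2$medians)
  expect_error(mtry_sweep(d$X, d$y, c(0, 3), replications = 2), "mtry")
  sc <- mtry_sweep(d$X, rep(1, 60), c(1, 3), replications = 2, ntree = 60)
  expect_true(all(is.na(sc$r2)))
})

test_that("ntree curve evaluates prefixes of one forest consistently", {
  sd_ <- small_signal_dataset(n = 100, p = 10, n_inf = 3, seed = 3)
  d <- sd_$dataset
  tr <- d$split == "train"; te <- d$split == "test"
  curve_a <- ntree_curve(d$X[tr, ], d$y[tr], d$X[te, ], d$y[te],
                         c(50, 100, 200), seed = 4)
  curve_b <- ntree_curve(d$X[tr, ], d$y[tr], d$X[te, ], d$y[te],
                         c(25, 200), seed = 4)
  # the shared largest count agrees between the two grids (same forest seed)
  expect_equal(curve_a$oob_mse[3], curve_b$oob_mse[2])
  expect_equal(curve_a$test_mse[3], curve_b$test_mse[2])
  # in-bag optimism: training error below OOB error at every count
  expect_true(all(curve_a$train_mse <= curve_a$oob_mse))
  expect_error(ntree_curve(d$X[tr, ], d$y[tr], d$X[te, ], d$y[te],
                           integer(0)), "empty")
  expect_error(ntree_curve(d$X[tr, ], d$y[tr], d$X[te, ], d$y[te],
                           c(100, 50)), "increasing")
})
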