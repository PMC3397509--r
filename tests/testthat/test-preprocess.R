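test_that("sparse-zero filter removes strictly above the threshold", {
  x <- make_matrix(c(c(rep(0, 9), 1),        # zero fraction 0.9 -> removed
                     c(rep(0, 8), 1, 2),     # zero fraction 0.8 -> kept
                     rep(0, 10),             # all zero -> removed
                     rnorm(10)), 10)
  res <- filter_sparse_zero(x, zero_fraction = 0.85)
  expect_equal(colnames(res$matrix), c("D002", "D004"))
  expect_setequal(res$report$removed$descriptor, c("D001", "D003"))
  expect_true(all(res$report$removed$rule == "sparse_zero"))
  # all columns removed is an error advising a threshold change
  expect_error(filter_sparse_zero(make_matrix(rep(0, 10), 10), 0.5),
               "zero_fraction")
})

test_that("near-zero-variance filter applies the two-rule definition", {
  x <- make_matrix(c(rep(7, 100),                    # constant -> removed
                     c(rep(0, 98), 1, 1),            # ratio 49, unique% 3 -> removed
                     seq_len(100) + 0,               # 100 distinct -> kept
                     rep(c(0, 1), 50)), 100)         # ratio 1 -> kept
  res <- filter_near_zero_variance(x)
  expect_equal(colnames(res$matrix), c("D003", "D004"))
  expect_setequal(res$report$removed$descriptor, c("D001", "D002"))
})

test_that("correlation filter prunes greedily with deterministic ties", {
  withr::with_seed(4, {
    a <- rnorm(30); b <- rnorm(30)
    # identical pair: tie on mean |r| -> the later column is dropped
    x <- make_matrix(c(a, a, b), 30)
    res <- filter_correlated(x, 0.75)
    expect_equal(colnames(res$matrix), c("D001", "D003"))
    expect_equal(res$report$removed$descriptor, "D002")

    # |r| = 0.5 pair survives at cutoff 0.75
    c2 <- 0.5 * scale(a)[, 1] + sqrt(0.75) * scale(resid(lm(b ~ a)))[, 1]
    x2 <- make_matrix(c(a, c2), 30)
    expect_lt(abs(cor(x2))[1, 2], 0.75)
    res2 <- filter_correlated(x2, 0.75)
    expect_equal(ncol(res2$matrix), 2)
  })
  # zero-variance column is an error naming the column
  xz <- make_matrix(c(rnorm(10), rep(1, 10)), 10)
  expect_error(filter_correlated(xz), "D002")
})

test_that("greedy pruning matches exhaustive minimal removal on a toy instance", {
  # 4 columns, exactly one pair above the cutoff; brute force over all
  # removal subsets finds the minimal set leaving max |r| <= cutoff
  withr::with_seed(11, {
    z <- rnorm(40)
    x <- make_matrix(c(z, 0.95 * z + 0.1 * rnorm(40), rnorm(40), rnorm(40)), 40)
  })
  cutoff <- 0.75
  ok <- function(cols) {
    if (length(cols) < 2) return(TRUE)
    cm <- abs(cor(x[, cols, drop = FALSE])); diag(cm) <- 0
    max(cm) <= cutoff
  }
  minimal <- NULL
  for (k in 0:3) {
    valid <- Filter(function(s) ok(setdiff(1:4, s)),
                    combn(4, k, simplify = FALSE))
    if (length(valid)) { minimal <- valid; break }
  }
  res <- filter_correlated(x, cutoff)
  removed_idx <- sort(match(res$report$removed$descriptor, colnames(x)))
  expect_true(any(vapply(minimal, function(s) identical(sort(s), removed_idx),
                         logical(1))))
  # and the greedy solution is of minimal size
  expect_equal(length(removed_idx), length(minimal[[1]]))
})

test_that("pipeline removes exactly the generator's planted violations", {
  g <- generate_qsar(synth_spec(n_compounds = 200, n_descriptors = 40,
                                n_informative = 5,
                                n_sparse_columns = 6,
                                sparse_zero_fraction = 0.95,
                                n_constant_columns = 3,
                                n_correlated_pairs = 4, correlation = 0.95,
                                seed = 8))
  res <- preprocess_pipeline(g$dataset$X)
  tr <- g$truth
  # constants always go (NZV rule); sparse columns at 95% zeros go (stage 1);
  # each 0.95-correlated decoy costs one member of its pair
  expect_true(all(tr$descriptor[tr$role == "constant"] %in%
                    res$report$removed$descriptor))
  sparse_removed <- res$report$removed$descriptor[
    res$report$removed$rule == "sparse_zero"]
  expect_true(all(sparse_removed %in% tr$descriptor[tr$role == "sparse"]))
  corr_removed <- res$report$removed$descriptor[
    res$report$removed$rule == "correlated"]
  expect_equal(length(corr_removed), 4)
  # ground-truth accounting: kept + removed partitions the input
  expect_setequal(c(res$report$removed$descriptor, colnames(res$matrix)),
                  colnames(g$dataset$X))
})

test_that("pipeline is idempotent, order-preserving, and bounds correlations", {
  x <- random_matrix(60, 25, seed = 5)
  res1 <- preprocess_pipeline(x)
  res2 <- preprocess_pipeline(res1$matrix)
  expect_identical(res1$matrix, res2$matrix)
  expect_equal(nrow(res2$report$removed), 0)
  # column order is a subsequence of the input order
  expect_identical(colnames(res1$matrix),
                   intersect(colnames(x), colnames(res1$matrix)))
  cm <- abs(cor(res1$matrix)); diag(cm) <- 0
  expect_lte(max(cm), 0.75)
  expect_error(preprocess_pipeline(x[, 0, drop = FALSE]))
})
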