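## The external-validation battery: conventional and PRESS-based r-squared
## statistics, through-origin diagnostics (k, r2_o), Roy's modified r2_m,
## the Tropsha acceptability gate, and Y-randomization.

#' Bundle observed and predicted activities
#'
#' @param y observed activities.
#' @param yhat predicted activities, same length.
#' @param reference_mean the mean used in PRESS-style denominators. For
#'   training/cross-validated statistics this is the training observed mean;
#'   for `r2_pred` on a test set it is the TRAINING set observed mean
#'   (defaults to `mean(y)`, which is only correct for training data).
#' @return object of class `prediction_set`.
#' @export
prediction_set <- function(y, yhat, reference_mean = mean(y)) {
  stopifnot(length(y) == length(yhat), length(y) >= 2,
            all(is.finite(y)), all(is.finite(yhat)),
            is.finite(reference_mean))
  structure(list(y = as.numeric(y), yhat = as.numeric(yhat),
                 reference_mean = reference_mean),
            class = "prediction_set")
}

#' Root mean squared error
#'
#' `sqrt(mean((y - yhat)^2))`.
#'
#' @param ps `prediction_set`.
#' @return non-negative scalar.
#' @export
rmse <- function(ps) {
  stopifnot(inherits(ps, "prediction_set"))
  sqrt(mean((ps$y - ps$yhat)^2))
}

#' Squared Pearson correlation between observed and predicted
#'
#' The conventional best-fit-line coefficient of determination (`r2_ncv` on
#' training resubstitution, `r2_ts` on a test set). Undefined (NA) when
#' either vector is constant.
#'
#' @param ps `prediction_set`.
#' @return scalar in `[0, 1]`, or NA when undefined.
#' @export
r2_pearson <- function(ps) {
  stopifnot(inherits(ps, "prediction_set"))
  if (stats::sd(ps$y) == 0 || stats::sd(ps$yhat) == 0) return(NA_real_)
  stats::cor(ps$y, ps$yhat)^2
}

#' PRESS-based coefficient of determination
#'
#' `1 - sum((y - yhat)^2) / sum((y - reference_mean)^2)`. With out-of-bag
#' predictions on the training set this is the cross-validated `r2_cv`; can
#' be negative when predictions are worse than the reference mean.
#'
#' @param ps `prediction_set`.
#' @return scalar `<= 1`.
#' @export
r2_press <- function(ps) {
  stopifnot(inherits(ps, "prediction_set"))
  denom <- sum((ps$y - ps$reference_mean)^2)
  if (denom == 0) stop("zero denominator: observations equal the reference mean",
                       call. = FALSE)
  1 - sum((ps$y - ps$yhat)^2) / denom
}

#' Predictive coefficient for an external test set
#'
#' `r2_pred = 1 - PRESS/SD` where PRESS sums squared test residuals and SD
#' sums squared deviations of the test observations from the TRAINING set
#' observed mean. The `prediction_set` must therefore carry the training
#' mean as `reference_mean`.
#'
#' @param test_ps `prediction_set` over test compounds with
#'   `reference_mean` set to the training observed mean.
#' @return scalar `<= 1`.
#' @export
r2_pred <- function(test_ps) r2_press(test_ps)

#' Through-origin regression diagnostics
#'
#' Least-squares regression of observed on predicted with the intercept
#' fixed at zero: slope `k = sum(y * yhat) / sum(yhat^2)` and its
#' determination coefficient
#' `r2_o = 1 - sum((y - k*yhat)^2) / sum((y - mean(y))^2)`,
#' the denominator using the test-set observed mean.
#'
#' @param test_ps `prediction_set` over the test compounds.
#' @return list with `k` and `r2_o`.
#' @export
origin_stats <- function(test_ps) {
  stopifnot(inherits(test_ps, "prediction_set"))
  ss_hat <- sum(test_ps$yhat^2)
  if (ss_hat == 0) stop("all predictions are zero", call. = FALSE)
  k <- sum(test_ps$y * test_ps$yhat) / ss_hat
  ss_tot <- sum((test_ps$y - mean(test_ps$y))^2)
  if (ss_tot == 0) stop("constant observed values", call. = FALSE)
  list(k = k, r2_o = 1 - sum((test_ps$y - k * test_ps$yhat)^2) / ss_tot)
}

#' Roy's modified external metric
#'
#' `r2_m = r2_ts * (1 - sqrt(r2_ts - r2_o))`, penalizing divergence between
#' the with-intercept and through-origin fits. Equals `r2_ts` when the two
#' agree and zero in the worst case. When `r2_o > r2_ts` (possible with
#' noisy inputs) the difference is clamped at zero with a warning.
#'
#' @param r2_ts conventional test-set determination coefficient.
#' @param r2_o through-origin determination coefficient.
#' @return scalar in `[0, r2_ts]`.
#' @export
r2_m <- function(r2_ts, r2_o) {
  diff <- r2_ts - r2_o
  if (diff < 0) {
    warning("r2_o exceeds r2_ts; clamping the difference at 0", call. = FALSE)
    diff <- 0
  }
  r2_ts * (1 - sqrt(diff))
}

#' Tropsha acceptability gate
#'
#' Four strict criteria for an externally predictive model:
#' `r2_pred > 0.5`; `r2_ts > 0.6`; `(r2_ts - r2_o)/r2_ts < 0.1`;
#' `0.85 <= k <= 1.15`. Overall pass requires all four.
#'
#' @param report `validation_report` (or any list carrying `r2_pred`,
#'   `r2_ts`, `r2_o`, `k`).
#' @return list of per-criterion logicals plus `overall`.
#' @export
tropsha_check <- function(report) {
  need <- c("r2_pred", "r2_ts", "r2_o", "k")
  if (!all(need %in% names(report)) ||
      any(!vapply(report[need], is.finite, logical(1))))
    stop("report must carry finite r2_pred, r2_ts, r2_o and k", call. = FALSE)
  out <- list(
    r2_pred_gt_0.5 = report$r2_pred > 0.5,
    r2_ts_gt_0.6 = report$r2_ts > 0.6,
    rel_diff_lt_0.1 = (report$r2_ts - report$r2_o) / report$r2_ts < 0.1,
    k_in_band = report$k >= 0.85 & report$k <= 1.15)
  out$overall <- all(unlist(out))
  out
}

#' Assemble the full validation report
#'
#' Combines training-set fit, optional cross-validated (out-of-bag)
#' statistics, and the external test battery into one report. All three
#' prediction sets must use the training observed mean as their
#' `reference_mean`.
#'
#' @param train_ps training resubstitution predictions.
#' @param oob_ps out-of-bag (or otherwise cross-validated) predictions on
#'   the training compounds, or `NULL` when unavailable.
#' @param test_ps external test predictions with the training mean as
#'   reference.
#' @return object of class `validation_report`: list with `r2_ncv`,
#'   `r2_cv`, `rmse_train`, `r2_ts`, `r2_pred`, `rmse_test`, `r2_o`, `k`,
#'   `r2_m`, `rel_diff`, `press`, `sd`, `n_train`, `n_test`, `tropsha`.
#' @export
full_report <- function(train_ps, oob_ps = NULL, test_ps) {
  stopifnot(inherits(train_ps, "prediction_set"),
            inherits(test_ps, "prediction_set"))
  os <- origin_stats(test_ps)
  r2ts <- r2_pearson(test_ps)
  rep <- list(
    r2_ncv = r2_pearson(train_ps),
    r2_cv = if (is.null(oob_ps)) NA_real_ else r2_press(oob_ps),
    rmse_train = rmse(train_ps),
    r2_ts = r2ts,
    r2_pred = r2_pred(test_ps),
    rmse_test = rmse(test_ps),
    r2_o = os$r2_o,
    k = os$k,
    r2_m = suppressWarnings(r2_m(r2ts, os$r2_o)),
    rel_diff = (r2ts - os$r2_o) / r2ts,
    press = sum((test_ps$y - test_ps$yhat)^2),
    sd = sum((test_ps$y - test_ps$reference_mean)^2),
    n_train = length(train_ps$y),
    n_test = length(test_ps$y))
  rep$tropsha <- tropsha_check(rep)
  structure(rep, class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat(sprintf("training  (n=%d): r2_ncv=%.3f r2_cv=%s rmse=%.3f\n",
              x$n_train, x$r2_ncv,
              ifelse(is.na(x$r2_cv), "NA", sprintf("%.3f", x$r2_cv)),
              x$rmse_train))
  cat(sprintf("test      (n=%d): r2_ts=%.3f r2_pred=%.3f rmse=%.3f\n",
              x$n_test, x$r2_ts, x$r2_pred, x$rmse_test))
  cat(sprintf("through-origin: k=%.3f r2_o=%.3f r2_m=%.3f rel_diff=%.3f\n",
              x$k, x$r2_o, x$r2_m, x$rel_diff))
  cat("Tropsha gate:", if (x$tropsha$overall) "PASS" else "FAIL", "\n")
  invisible(x)
}

#' Build a validation report from the packaged benchmark
#'
#' Recomputes the full battery from the packaged 190-compound FBPase fixture
#' for either prediction column, using its published 126/64 train/test
#' membership. No cross-validated column is available in the fixture, so
#' `r2_cv` is NA.
#'
#' @param model `"garf"` (GA-selected model predictions) or `"rf"`
#'   (full-descriptor model predictions).
#' @return `validation_report`.
#' @export
fixture_report <- function(model = c("garf", "rf")) {
  model <- match.arg(model)
  df <- load_table3_fixture()
  pred <- if (model == "garf") df$garf_pred else df$rf_pred
  tr <- !df$is_test
  y_tr_mean <- mean(df$observed[tr])
  full_report(
    train_ps = prediction_set(df$observed[tr], pred[tr], y_tr_mean),
    oob_ps = NULL,
    test_ps = prediction_set(df$observed[!tr], pred[!tr], y_tr_mean))
}

#' RF modeling procedure for use in Y-randomization and pipelines
#'
#' Returns a closure that fits a random forest on a dataset's training split
#' (optionally restricted to a descriptor mask), predicts the test split,
#' and returns the [full_report()]. Used as the refitting procedure inside
#' [y_randomization()] and by the end-to-end pipeline.
#'
#' @param ntree trees.
#' @param mask optional 0/1 vector (or descriptor names) restricting the
#'   columns used.
#' @param seed forest seed.
#' @return function(dataset) -> `validation_report`.
#' @export
rf_procedure <- function(ntree = 500, mask = NULL, seed = 1) {
  function(dataset) {
    stopifnot(inherits(dataset, "qsar_dataset"))
    X <- dataset$X
    if (!is.null(mask)) {
      cols <- if (is.character(mask)) mask else which(mask == 1)
      X <- X[, cols, drop = FALSE]
    }
    tr <- dataset$split == "train"; te <- dataset$split == "test"
    if (!any(tr) || !any(te))
      stop("dataset needs both train and test compounds", call. = FALSE)
    m <- fit_forest(X[tr, , drop = FALSE], dataset$y[tr], ntree = ntree,
                    seed = seed)
    y_tr_mean <- mean(dataset$y[tr])
    full_report(
      train_ps = prediction_set(dataset$y[tr],
                                predict(m, X[tr, , drop = FALSE]), y_tr_mean),
      oob_ps = prediction_set(dataset$y[tr], m$oob, y_tr_mean),
      test_ps = prediction_set(dataset$y[te],
                               predict(m, X[te, , drop = FALSE]), y_tr_mean))
  }
}

#' Y-randomization check
#'
#' Repeatedly permutes the training activities (test activities stay fixed),
#' refits the supplied modeling procedure on the shuffled labels, and
#' collects the full statistic set. A real model's statistics should
#' collapse under permutation (low r2, inflated RMSE); if they do not, the
#' original fit is suspect of chance correlation.
#'
#' @param dataset `qsar_dataset` with train and test splits.
#' @param procedure function(dataset) -> `validation_report`, e.g.
#'   [rf_procedure()].
#' @param rounds number of permutation rounds (500 in a full study; scale
#'   down for quick checks).
#' @param seed integer; round r permutes with seed `seed + r`.
#' @param identity_round if TRUE, skip permutation (single round) -- a
#'   consistency hook: the result must equal the unpermuted report.
#' @return object of class `yrand_result`: list with `per_round`
#'   (data.frame) and `means` (named vector).
#' @export
y_randomization <- function(dataset, procedure, rounds = 500, seed = 1,
                            identity_round = FALSE) {
  stopifnot(inherits(dataset, "qsar_dataset"), rounds >= 1)
  stats_names <- c("r2_ncv", "r2_cv", "rmse_train", "r2_ts", "r2_pred",
                   "r2_m", "rmse_test")
  if (identity_round) rounds <- 1
  rows <- vector("list", rounds)
  tr <- which(dataset$split == "train")
  for (r in seq_len(rounds)) {
    d <- dataset
    if (!identity_round) {
      perm <- withr::with_seed(seed + r, sample(tr))
      y2 <- d$y
      y2[tr] <- unname(d$y[perm])
      d <- qsar_dataset(d$X, stats::setNames(y2, names(d$y)), d$split)
    }
    rep <- procedure(d)
    rows[[r]] <- as.data.frame(rep[stats_names])
  }
  per_round <- do.call(rbind, rows)
  structure(list(per_round = per_round,
                 means = colMeans(per_round), rounds = rounds, seed = seed),
            class = "yrand_result")
}

#' @export
print.yrand_result <- function(x, ...) {
  cat(sprintf("Y-randomization, %d rounds; mean statistics:\n", x$rounds))
  print(round(x$means, 3))
  invisible(x)
}
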