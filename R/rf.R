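## Random-forest regression engine. The tree ensemble itself is delegated to
## the randomForest package (unpruned CART regression trees, one bootstrap
## per tree); this module owns the out-of-bag contracts, the importance
## surface, and the two tuning experiments (mtry sweep, ntree curve).

#' Default mtry for regression forests
#'
#' One third of the descriptor count, floored, never below 1: 13 for 40
#' descriptors, 36 for 108.
#'
#' @param p number of descriptors.
#' @return integer.
#' @export
default_mtry <- function(p) max(1L, floor(p / 3))

#' Fit a random-forest regression model
#'
#' Trees are unpruned CART regression trees grown on independent bootstrap
#' samples; the forest prediction is the mean over trees. Out-of-bag (OOB)
#' predictions aggregate, for each compound, only the trees whose bootstrap
#' excluded it; compounds that were in-bag for every tree carry a missing
#' flag rather than a silent zero.
#'
#' @param X descriptor matrix.
#' @param y activity vector aligned with `rownames(X)`.
#' @param ntree number of trees (default 500).
#' @param mtry split candidates per node; default `floor(p/3)`.
#' @param seed integer seed; fitting is deterministic for a fixed seed.
#' @param nodesize minimum node size (default 5, the regression standard).
#' @return object of class `forest_model`: list with the fitted `rf`,
#'   `oob` predictions (NA where flagged), `oob_missing` (logical),
#'   `ntree`, `mtry`, `seed`, and the training `y`.
#' @export
fit_forest <- function(X, y, ntree = 500, mtry = default_mtry(ncol(X)),
                       seed = 1, nodesize = 5) {
  validate_descriptor_matrix(X)
  p <- ncol(X)
  if (p == 0) stop("no descriptors", call. = FALSE)
  if (nrow(X) < 2) stop("need at least 2 compounds", call. = FALSE)
  if (length(y) != nrow(X)) stop("y must match rows of X", call. = FALSE)
  if (mtry < 1 || mtry > p) stop("mtry must be in [1, ", p, "]", call. = FALSE)
  rf <- withr::with_seed(seed, withCallingHandlers(
    randomForest::randomForest(X, y, ntree = ntree, mtry = mtry,
                               nodesize = nodesize, importance = TRUE,
                               keep.forest = TRUE, keep.inbag = TRUE),
    # degenerate responses (e.g. constant y) are handled by our own guards
    warning = function(w) {
      if (grepl("five or fewer unique values", conditionMessage(w)))
        invokeRestart("muffleWarning")
    }))
  oob <- unname(rf$predicted)
  missing <- !is.finite(oob)
  structure(list(rf = rf, oob = oob, oob_missing = missing,
                 ntree = ntree, mtry = mtry, seed = seed,
                 y = y, descriptors = colnames(X)),
            class = "forest_model")
}

#' @export
print.forest_model <- function(x, ...) {
  cat(sprintf("random forest: %d trees, mtry = %d, %d descriptors, %d compounds\n",
              x$ntree, x$mtry, length(x$descriptors), length(x$y)))
  invisible(x)
}

#' Predict from a forest model
#'
#' @param object `forest_model`.
#' @param newdata descriptor matrix.
#' @param ... unused.
#' @return numeric vector of predictions.
#' @export
predict.forest_model <- function(object, newdata, ...) {
  unname(stats::predict(object$rf, newdata))
}

#' Out-of-bag mean squared error
#'
#' @param model `forest_model`.
#' @param y observed activities; defaults to the training activities stored
#'   in the model.
#' @return mean squared difference between `y` and the OOB predictions.
#' @export
oob_mse <- function(model, y = model$y) {
  stopifnot(inherits(model, "forest_model"))
  if (any(model$oob_missing))
    stop("compound(s) without any out-of-bag prediction: ",
         paste(which(model$oob_missing), collapse = ", "),
         "; grow more trees", call. = FALSE)
  mean((y - model$oob)^2)
}

#' Out-of-bag squared Pearson correlation
#'
#' `r2_oob`, the squared Pearson correlation between observed activities and
#' their OOB predictions. Undefined (NA) when either side is constant.
#'
#' @inheritParams oob_mse
#' @return numeric scalar, or NA when undefined.
#' @export
oob_r2 <- function(model, y = model$y) {
  stopifnot(inherits(model, "forest_model"))
  if (any(model$oob_missing))
    stop("compound(s) without any out-of-bag prediction", call. = FALSE)
  if (stats::sd(y) == 0 || stats::sd(model$oob) == 0) return(NA_real_)
  stats::cor(y, model$oob)^2
}

#' Variable importance table
#'
#' Two measures: `inc_mse_pct` (%IncMSE) is the mean over trees of the OOB
#' MSE increase after permuting the descriptor, normalized by its standard
#' error; `inc_node_purity` (IncNodePurity) is the total decrease in node
#' sum-of-squares attributed to splits on the descriptor. Higher means more
#' important; a descriptor never chosen at any split has zero node purity.
#'
#' @param model `forest_model`.
#' @return data.frame with columns `descriptor`, `inc_mse_pct`,
#'   `inc_node_purity`, in descriptor order.
#' @export
variable_importance <- function(model) {
  stopifnot(inherits(model, "forest_model"))
  imp <- randomForest::importance(model$rf, scale = TRUE)
  data.frame(descriptor = rownames(imp),
             inc_mse_pct = unname(imp[, "%IncMSE"]),
             inc_node_purity = unname(imp[, "IncNodePurity"]),
             stringsAsFactors = FALSE)
}

#' Sweep mtry and record OOB correlation distributions
#'
#' For each candidate `mtry`, refits the forest `replications` times (with
#' distinct derived seeds) and records `r2_oob` each time. Medians summarize
#' the distributions, mirroring the usual boxplot presentation.
#'
#' @param X,y training data.
#' @param mtry_values integer vector of candidate values.
#' @param replications number of refits per value (>= 2).
#' @param ntree trees per refit (default 100, sufficient for tuning).
#' @param seed base seed; replicate r uses `seed + r`.
#' @return object of class `mtry_sweep`: list with `r2` (replications x
#'   values matrix) and `medians` (named vector).
#' @export
mtry_sweep <- function(X, y, mtry_values, replications = 50, ntree = 100,
                       seed = 1) {
  stopifnot(replications >= 2)
  p <- ncol(X)
  if (any(mtry_values < 1 | mtry_values > p))
    stop("mtry values must lie in [1, ", p, "]", call. = FALSE)
  r2 <- matrix(NA_real_, replications, length(mtry_values),
               dimnames = list(NULL, as.character(mtry_values)))
  for (r in seq_len(replications)) {
    for (k in seq_along(mtry_values)) {
      m <- fit_forest(X, y, ntree = ntree, mtry = mtry_values[k],
                      seed = seed + r)
      r2[r, k] <- oob_r2(m)
    }
  }
  structure(list(r2 = r2, medians = apply(r2, 2, stats::median),
                 mtry_values = mtry_values),
            class = "mtry_sweep")
}

#' @export
print.mtry_sweep <- function(x, ...) {
  cat("median r2_oob by mtry:\n")
  print(round(x$medians, 4))
  invisible(x)
}

#' MSE trajectories as the forest grows
#'
#' Grows a single forest at the largest requested tree count and evaluates
#' prefixes of it, rather than refitting per count: OOB and test
#' trajectories come from the cumulative ensembles, and the training
#' trajectory from prefix-averaged per-tree predictions.
#'
#' @param X_train,y_train,X_test,y_test training and test data.
#' @param tree_counts sorted increasing vector of tree counts to report.
#' @param seed forest seed.
#' @param mtry split candidates (default `floor(p/3)`).
#' @return object of class `ntree_curve`: data.frame with columns `ntree`,
#'   `oob_mse`, `train_mse`, `test_mse`.
#' @export
ntree_curve <- function(X_train, y_train, X_test, y_test, tree_counts,
                        seed = 1, mtry = default_mtry(ncol(X_train))) {
  if (!length(tree_counts)) stop("empty tree_counts", call. = FALSE)
  if (is.unsorted(tree_counts, strictly = TRUE))
    stop("tree_counts must be strictly increasing", call. = FALSE)
  max_t <- max(tree_counts)
  rf <- withr::with_seed(seed,
    randomForest::randomForest(X_train, y_train, ntree = max_t, mtry = mtry,
                               nodesize = 5, xtest = X_test, ytest = y_test,
                               keep.forest = TRUE, keep.inbag = TRUE))
  # per-tree predictions on the training set, prefix-averaged
  ind <- stats::predict(rf, X_train, predict.all = TRUE)$individual
  prefix_mean <- t(apply(ind, 1, cumsum)) / rep(seq_len(max_t), each = nrow(ind))
  train_mse <- colMeans((prefix_mean - y_train)^2)
  out <- data.frame(ntree = tree_counts,
                    oob_mse = rf$mse[tree_counts],
                    train_mse = train_mse[tree_counts],
                    test_mse = rf$test$mse[tree_counts])
  class(out) <- c("ntree_curve", "data.frame")
  out
}
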