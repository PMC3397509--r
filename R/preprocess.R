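## Descriptor filters. Each filter returns list(matrix=, report=) where the
## report records every removal with its rule and a human-readable detail.
## Removal rules are deterministic, including tie-breaks, so a pipeline run
## is exactly reproducible.

new_filter_report <- function(removed, kept) {
  stopifnot(is.data.frame(removed),
            all(c("descriptor", "rule", "detail") %in% names(removed)))
  structure(list(removed = removed, kept = kept), class = "filter_report")
}

empty_removed <- function() {
  data.frame(descriptor = character(), rule = character(),
             detail = character(), stringsAsFactors = FALSE)
}

#' @export
print.filter_report <- function(x, ...) {
  cat(sprintf("filter report: %d kept, %d removed\n",
              length(x$kept), nrow(x$removed)))
  if (nrow(x$removed)) print(table(x$removed$rule))
  invisible(x)
}

#' Remove descriptors dominated by zeros
#'
#' A descriptor column is removed when its fraction of exact zeros exceeds
#' `zero_fraction` (strictly). Surviving column order is preserved.
#'
#' @param x descriptor matrix.
#' @param zero_fraction threshold in (0, 1]; default 0.85.
#' @return list with elements `matrix` (filtered) and `report`
#'   (`filter_report`).
#' @export
filter_sparse_zero <- function(x, zero_fraction = 0.85) {
  validate_descriptor_matrix(x)
  stopifnot(zero_fraction > 0, zero_fraction <= 1)
  frac <- colMeans(x == 0)
  drop <- frac > zero_fraction
  if (all(drop))
    stop("all descriptors exceed the zero fraction threshold; raise zero_fraction",
         call. = FALSE)
  removed <- if (!any(drop)) empty_removed() else data.frame(
    descriptor = colnames(x)[drop], rule = "sparse_zero",
    detail = sprintf("zero fraction %.3f > %.3f", frac[drop], zero_fraction),
    stringsAsFactors = FALSE)
  list(matrix = x[, !drop, drop = FALSE],
       report = new_filter_report(removed, colnames(x)[!drop]))
}

#' Remove zero- and near-zero-variance descriptors
#'
#' A column is removed when it is constant, or when the ratio of the most
#' frequent value's count to the second most frequent value's count exceeds
#' `freq_ratio_cutoff` while the percentage of distinct values is below
#' `unique_percent_cutoff`. Defaults correspond to the common 95/5 frequency
#' rule with a 10% distinctness floor.
#'
#' @param x descriptor matrix.
#' @param freq_ratio_cutoff default 19 (i.e. 95/5).
#' @param unique_percent_cutoff default 10 (percent of rows).
#' @return list with `matrix` and `report`.
#' @export
filter_near_zero_variance <- function(x, freq_ratio_cutoff = 19,
                                      unique_percent_cutoff = 10) {
  validate_descriptor_matrix(x)
  n <- nrow(x)
  stats <- apply(x, 2, function(col) {
    counts <- sort(table(col), decreasing = TRUE)
    uniq_pct <- 100 * length(counts) / n
    if (length(counts) == 1) return(c(Inf, uniq_pct))
    c(counts[1] / counts[2], uniq_pct)
  })
  freq_ratio <- stats[1, ]
  uniq_pct <- stats[2, ]
  constant <- !is.finite(freq_ratio) | uniq_pct == 100 / n
  nzv <- freq_ratio > freq_ratio_cutoff & uniq_pct < unique_percent_cutoff
  drop <- constant | nzv
  detail <- ifelse(constant, "constant",
                   sprintf("freq ratio %.1f > %.1f and unique%% %.1f < %.1f",
                           freq_ratio, freq_ratio_cutoff,
                           uniq_pct, unique_percent_cutoff))
  removed <- if (!any(drop)) empty_removed() else
    data.frame(descriptor = colnames(x)[drop],
               rule = "near_zero_variance",
               detail = detail[drop], stringsAsFactors = FALSE)
  if (all(drop))
    stop("all descriptors are (near) zero-variance", call. = FALSE)
  list(matrix = x[, !drop, drop = FALSE],
       report = new_filter_report(removed, colnames(x)[!drop]))
}

#' Prune highly correlated descriptor pairs
#'
#' Greedy elimination on the absolute Pearson correlation matrix: while any
#' off-diagonal |r| exceeds `cutoff`, the pair with the largest |r| is found
#' and the member with the larger mean absolute correlation to all remaining
#' columns is dropped (ties drop the later column in input order). On return
#' no surviving pair has |r| > cutoff.
#'
#' Zero-variance columns have no defined correlation and must be removed
#' beforehand (see [filter_near_zero_variance()]); encountering one is an
#' error.
#'
#' @param x descriptor matrix with at least 2 rows.
#' @param cutoff absolute correlation threshold in (0, 1); default 0.75.
#' @return list with `matrix` and `report`.
#' @export
filter_correlated <- function(x, cutoff = 0.75) {
  validate_descriptor_matrix(x)
  stopifnot(cutoff > 0, cutoff < 1, nrow(x) >= 2)
  sds <- apply(x, 2, stats::sd)
  if (any(sds == 0))
    stop("zero-variance descriptor(s) must be filtered first: ",
         paste(colnames(x)[sds == 0], collapse = ", "), call. = FALSE)
  cm <- abs(stats::cor(x))
  diag(cm) <- 0
  alive <- rep(TRUE, ncol(x))
  removed <- empty_removed()
  repeat {
    sub <- cm[alive, alive, drop = FALSE]
    if (!length(sub) || max(sub) <= cutoff) break
    idx_alive <- which(alive)
    worst <- which(sub == max(sub), arr.ind = TRUE)[1, ]
    i <- idx_alive[worst[1]]; j <- idx_alive[worst[2]]
    mean_i <- mean(cm[i, alive])
    mean_j <- mean(cm[j, alive])
    # larger mean absolute correlation loses; ties drop the later column
    drop <- if (mean_i > mean_j) i else if (mean_j > mean_i) j else max(i, j)
    keep <- if (drop == i) j else i
    removed <- rbind(removed, data.frame(
      descriptor = colnames(x)[drop], rule = "correlated",
      detail = sprintf("|r| = %.3f with %s > %.2f", cm[i, j],
                       colnames(x)[keep], cutoff),
      stringsAsFactors = FALSE))
    alive[drop] <- FALSE
  }
  list(matrix = x[, alive, drop = FALSE],
       report = new_filter_report(removed, colnames(x)[alive]))
}

#' Full descriptor preprocessing pipeline
#'
#' Applies the three filters in order: sparse-zero removal, near-zero-variance
#' removal, correlation pruning. The merged report records every removal with
#' the rule responsible; per-stage column counts are printed when `verbose`.
#' The pipeline is idempotent: applying it twice gives the same matrix as
#' applying it once.
#'
#' @param x descriptor matrix.
#' @param zero_fraction passed to [filter_sparse_zero()].
#' @param freq_ratio_cutoff,unique_percent_cutoff passed to
#'   [filter_near_zero_variance()].
#' @param corr_cutoff passed to [filter_correlated()].
#' @param verbose print per-stage counts.
#' @return list with `matrix` and `report`.
#' @export
preprocess_pipeline <- function(x, zero_fraction = 0.85,
                                freq_ratio_cutoff = 19,
                                unique_percent_cutoff = 10,
                                corr_cutoff = 0.75, verbose = FALSE) {
  validate_descriptor_matrix(x)
  if (!ncol(x) || !nrow(x)) stop("empty descriptor matrix", call. = FALSE)
  s1 <- filter_sparse_zero(x, zero_fraction)
  s2 <- filter_near_zero_variance(s1$matrix, freq_ratio_cutoff,
                                  unique_percent_cutoff)
  s3 <- filter_correlated(s2$matrix, corr_cutoff)
  if (verbose)
    message(sprintf("descriptors: %d -> %d (sparse zero) -> %d (near zero var) -> %d (correlation)",
                    ncol(x), ncol(s1$matrix), ncol(s2$matrix), ncol(s3$matrix)))
  removed <- rbind(s1$report$removed, s2$report$removed, s3$report$removed)
  stopifnot(length(intersect(removed$descriptor, colnames(s3$matrix))) == 0,
            nrow(removed) + ncol(s3$matrix) == ncol(x))
  list(matrix = s3$matrix, report = new_filter_report(removed, colnames(s3$matrix)))
}
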