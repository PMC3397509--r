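## Seeded synthetic-data generators with known ground truth. The activity is
## linear in a small informative subset of standard-normal descriptors plus
## Gaussian noise, so the population R^2 is analytic:
## R^2 = sum(beta^2) / (sum(beta^2) + noise_sd^2). Decoy columns (pure noise,
## correlated near-duplicates, zero-inflated sparse columns, constants) make
## preprocessing, SOM splitting and GA recovery testable without any
## external data.

#' Specification for a synthetic QSAR dataset
#'
#' Defaults describe the package's standard test-scale problem: 150
#' compounds, 100 descriptors of which 10 are informative with unit
#' coefficients, and `noise_sd = sqrt(2.5)` giving a population R^2 of
#' exactly 10/12.5 = 0.8. Structural decoys are off by default and switched
#' on explicitly where a test needs them.
#'
#' @param n_compounds,n_descriptors dataset shape.
#' @param n_informative number of activity-carrying descriptors.
#' @param beta coefficient vector (length `n_informative`).
#' @param noise_sd standard deviation of the additive activity noise.
#' @param n_sparse_columns zero-inflated decoy columns.
#' @param sparse_zero_fraction expected zero fraction of sparse columns.
#' @param n_correlated_pairs decoys correlated with informative columns.
#' @param correlation target correlation of those decoys.
#' @param n_constant_columns constant decoy columns.
#' @param n_clusters,cluster_separation blob structure for SOM tests (see
#'   [generate_clustered()]).
#' @param seed integer seed; generation is a pure function of the spec.
#' @return list of class `synth_spec`.
#' @export
synth_spec <- function(n_compounds = 150, n_descriptors = 100,
                       n_informative = 10, beta = rep(1, n_informative),
                       noise_sd = sqrt(2.5),
                       n_sparse_columns = 0, sparse_zero_fraction = 0.9,
                       n_correlated_pairs = 0, correlation = 0.9,
                       n_constant_columns = 0,
                       n_clusters = 1, cluster_separation = 0, seed = 1) {
  stopifnot(n_compounds >= 2, n_informative >= 1,
            length(beta) == n_informative, noise_sd >= 0,
            sparse_zero_fraction > 0, sparse_zero_fraction < 1,
            correlation > -1, correlation < 1, n_clusters >= 1)
  structured <- n_informative + n_sparse_columns + n_correlated_pairs +
    n_constant_columns
  if (structured > n_descriptors)
    stop("column roles exceed n_descriptors (", structured, " > ",
         n_descriptors, ")", call. = FALSE)
  rm(structured)  # correlated decoys shadow informative columns cyclically
  structure(as.list(environment()), class = "synth_spec")
}

#' Population R-squared implied by a synthetic spec
#'
#' @param spec `synth_spec`.
#' @return `sum(beta^2) / (sum(beta^2) + noise_sd^2)`.
#' @export
population_r2 <- function(spec) {
  stopifnot(inherits(spec, "synth_spec"))
  s <- sum(spec$beta^2)
  s / (s + spec$noise_sd^2)
}

#' Generate a synthetic QSAR dataset with known ground truth
#'
#' Informative descriptors are i.i.d. standard normal and the activity is
#' `y = X beta + eps`. Decoy roles: `noise` (standard normal), `correlated`
#' (decoy = rho * informative + sqrt(1-rho^2) * noise), `sparse`
#' (zero-inflated normal) and `constant`. Roles are assigned to shuffled
#' column positions and recorded in the returned truth table; descriptor
#' names follow the `D###` convention.
#'
#' @param spec `synth_spec`.
#' @return list with `dataset` (`qsar_dataset`, split unassigned) and
#'   `truth` (data.frame: `descriptor`, `role`, `beta`, plus attribute
#'   `population_r2`).
#' @export
generate_qsar <- function(spec) {
  stopifnot(inherits(spec, "synth_spec"))
  n <- spec$n_compounds; p <- spec$n_descriptors
  withr::with_seed(spec$seed, {
    roles <- rep("noise", p)
    slots <- sample.int(p)  # shuffled positions for the structured roles
    take <- function(k) { out <- slots[seq_len(k)]; slots <<- slots[-seq_len(k)]; out }
    inf_idx <- if (spec$n_informative) take(spec$n_informative) else integer()
    cor_idx <- if (spec$n_correlated_pairs) take(spec$n_correlated_pairs) else integer()
    spa_idx <- if (spec$n_sparse_columns) take(spec$n_sparse_columns) else integer()
    con_idx <- if (spec$n_constant_columns) take(spec$n_constant_columns) else integer()
    roles[inf_idx] <- "informative"; roles[cor_idx] <- "correlated"
    roles[spa_idx] <- "sparse"; roles[con_idx] <- "constant"
    X <- matrix(stats::rnorm(n * p), n, p)
    rho <- spec$correlation
    for (j in seq_along(cor_idx))
      X[, cor_idx[j]] <- rho * X[, inf_idx[(j - 1) %% length(inf_idx) + 1]] +
        sqrt(1 - rho^2) * stats::rnorm(n)
    for (j in spa_idx)
      X[, j] <- X[, j] * (stats::runif(n) > spec$sparse_zero_fraction)
    X[, con_idx] <- 1
    y <- drop(X[, inf_idx, drop = FALSE] %*% spec$beta) +
      stats::rnorm(n, 0, spec$noise_sd)
    dimnames(X) <- list(sprintf("c%03d", seq_len(n)),
                        sprintf("D%03d", seq_len(p)))
    beta_full <- numeric(p); beta_full[inf_idx] <- spec$beta
    truth <- data.frame(descriptor = colnames(X), role = roles,
                        beta = beta_full, stringsAsFactors = FALSE)
    attr(truth, "population_r2") <- population_r2(spec)
    list(dataset = qsar_dataset(X, stats::setNames(y, rownames(X))),
         truth = truth)
  })
}

#' Generate clustered descriptor data for SOM tests
#'
#' Gaussian blobs with unit within-cluster spread around centers placed at
#' the requested separation (each center is a random direction scaled to
#' norm `cluster_separation / 2`, so distinct centers are on the order of
#' `cluster_separation` apart).
#'
#' @param spec `synth_spec`; uses `n_compounds`, `n_descriptors`,
#'   `n_clusters`, `cluster_separation`, `seed`.
#' @return list with `matrix` (descriptor matrix) and `labels` (integer
#'   cluster per compound).
#' @export
generate_clustered <- function(spec) {
  stopifnot(inherits(spec, "synth_spec"))
  n <- spec$n_compounds; p <- spec$n_descriptors; k <- spec$n_clusters
  withr::with_seed(spec$seed, {
    centers <- matrix(stats::rnorm(k * p), k, p)
    if (k > 1 && spec$cluster_separation > 0)
      centers <- centers / sqrt(rowSums(centers^2)) *
        (spec$cluster_separation / 2)
    labels <- sort(rep_len(seq_len(k), n))
    X <- centers[labels, , drop = FALSE] + matrix(stats::rnorm(n * p), n, p)
    dimnames(X) <- list(sprintf("c%03d", seq_len(n)),
                        sprintf("D%03d", seq_len(p)))
    list(matrix = X, labels = labels)
  })
}
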