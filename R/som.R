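## Kohonen self-organizing map for rational dataset splitting. A small online
## SOM: winner-take-most updates with a Gaussian neighborhood whose radius
## decays linearly from max(rows, cols)/2 to 1 and a learning rate decaying
## linearly from 0.5 to 0.01. Descriptors are standardized (zero mean, unit
## variance) inside the map only; model fitting elsewhere uses raw values.

#' Construct a SOM grid object
#'
#' Mostly used internally by [train_som()]; exposed so that a codebook can be
#' built directly (e.g. in tests or to reuse a map trained elsewhere).
#'
#' @param codebook numeric matrix, one row per map unit, columns = descriptors.
#' @param rows,cols grid shape; `rows * cols` must equal `nrow(codebook)`.
#' @param center,scale standardization parameters applied to inputs before
#'   distance computation (per descriptor).
#' @return object of class `som_grid`.
#' @export
som_grid <- function(codebook, rows, cols,
                     center = rep(0, ncol(codebook)),
                     scale = rep(1, ncol(codebook))) {
  stopifnot(is.matrix(codebook), all(is.finite(codebook)),
            rows >= 1, cols >= 1, nrow(codebook) == rows * cols,
            length(center) == ncol(codebook), length(scale) == ncol(codebook))
  structure(list(codebook = codebook, rows = rows, cols = cols,
                 center = center, scale = scale),
            class = "som_grid")
}

#' @export
print.som_grid <- function(x, ...) {
  cat(sprintf("SOM grid: %d x %d units, %d descriptors\n",
              x$rows, x$cols, ncol(x$codebook)))
  invisible(x)
}

#' Train a self-organizing map on descriptor space
#'
#' @param x descriptor matrix (compounds in rows).
#' @param rows,cols grid shape; default 6 x 6 = 36 units.
#' @param epochs total number of single-sample presentation steps; default
#'   `500 * rows * cols`.
#' @param seed integer seed; training is deterministic for a fixed seed.
#' @return `som_grid` with the trained codebook and the standardization
#'   parameters used.
#' @export
train_som <- function(x, rows = 6, cols = 6, epochs = 500 * rows * cols,
                      seed = 1) {
  validate_descriptor_matrix(x)
  if (nrow(x) < 2) stop("need at least 2 compounds to train a map", call. = FALSE)
  ctr <- colMeans(x)
  scl <- apply(x, 2, stats::sd)
  if (all(scl == 0)) stop("constant descriptor matrix", call. = FALSE)
  scl[scl == 0] <- 1  # constant columns contribute nothing to distances
  z <- scale(x, center = ctr, scale = scl)
  n_units <- rows * cols
  # unit coordinates on the grid, row-major
  coord <- cbind(rep(seq_len(rows), each = cols), rep(seq_len(cols), rows))
  grid_d2 <- as.matrix(stats::dist(coord))^2
  r0 <- max(rows, cols) / 2
  withr::with_seed(seed, {
    codebook <- z[sample.int(nrow(z), n_units, replace = TRUE), , drop = FALSE]
    rownames(codebook) <- NULL
    order_idx <- unlist(lapply(seq_len(ceiling(epochs / nrow(z))),
                               function(i) sample.int(nrow(z))))[seq_len(epochs)]
    for (t in seq_len(epochs)) {
      frac <- (t - 1) / max(1, epochs - 1)
      alpha <- 0.5 + frac * (0.01 - 0.5)
      radius <- r0 + frac * (1 - r0)
      v <- z[order_idx[t], ]
      diff <- sweep(codebook, 2, v, "-")
      bmu <- which.min(rowSums(diff^2))
      h <- exp(-grid_d2[bmu, ] / (2 * radius^2))
      codebook <- codebook - (alpha * h) * diff
    }
    som_grid(codebook, rows, cols, ctr, scl)
  })
}

#' Map compounds to their best-matching units
#'
#' Each compound is assigned the map unit whose codebook vector is nearest in
#' Euclidean distance (after the grid's standardization); ties go to the
#' lowest unit index.
#'
#' @param grid `som_grid`.
#' @param x descriptor matrix with the same descriptor dimensionality the
#'   grid was trained on.
#' @return integer vector of unit indices (1-based, row-major), named by
#'   compound.
#' @export
map_to_bmu <- function(grid, x) {
  stopifnot(inherits(grid, "som_grid"))
  validate_descriptor_matrix(x)
  if (ncol(x) != ncol(grid$codebook))
    stop("dimension mismatch: grid has ", ncol(grid$codebook),
         " descriptors, matrix has ", ncol(x), call. = FALSE)
  z <- scale(x, center = grid$center, scale = grid$scale)
  cb2 <- rowSums(grid$codebook^2)
  # squared distance = |z|^2 - 2 z.w + |w|^2; |z|^2 constant per compound
  d2 <- sweep(-2 * z %*% t(grid$codebook), 2, cb2, "+")
  bmu <- apply(d2, 1, which.min)  # which.min takes the lowest index on ties
  stats::setNames(as.integer(bmu), rownames(x))
}

#' Split compounds into training and test sets from SOM occupancy
#'
#' Test compounds are drawn per occupied map unit proportionally to the
#' unit's occupancy, with largest-remainder rounding so the requested test
#' size is hit exactly. Every unit with at least 2 members keeps at least one
#' training compound, and singleton units always go to training, so the two
#' sets jointly cover the occupied map. Per-unit quotas are a deterministic
#' function of the occupancy alone; the seed only affects which compounds are
#' drawn within a unit.
#'
#' @param bmu named integer vector of unit assignments (from [map_to_bmu()]).
#' @param test_size number of test compounds, `0 < test_size < length(bmu)`.
#' @param seed integer seed for within-unit sampling.
#' @return data.frame with columns `compound_id`, `bmu`, `label`
#'   (train/test).
#' @export
split_by_som <- function(bmu, test_size, seed = 1) {
  n <- length(bmu)
  if (test_size <= 0 || test_size >= n)
    stop("test_size must be strictly between 0 and the number of compounds",
         call. = FALSE)
  occ <- table(bmu)
  units <- as.integer(names(occ))
  n_u <- as.integer(occ)
  cap <- ifelse(n_u >= 2, n_u - 1L, 0L)
  if (sum(cap) < test_size)
    stop("test_size ", test_size, " incompatible with keeping one training ",
         "compound per occupied unit (max feasible ", sum(cap), ")",
         call. = FALSE)
  exact <- test_size * n_u / n
  quota <- pmin(floor(exact), cap)
  remainder <- exact - floor(exact)
  pref <- order(-remainder, units)  # largest remainder first, unit index ties
  while (sum(quota) < test_size) {
    placed <- FALSE
    for (u in pref) {
      if (quota[u] < cap[u]) {
        quota[u] <- quota[u] + 1L
        placed <- TRUE
        if (sum(quota) == test_size) break
      }
    }
    if (!placed) stop("internal: cannot place test quota", call. = FALSE)
  }
  label <- stats::setNames(rep("train", n), names(bmu))
  withr::with_seed(seed, {
    for (k in seq_along(units)) {
      if (quota[k] == 0) next
      members <- names(bmu)[bmu == units[k]]
      label[sample(members, quota[k])] <- "test"
    }
  })
  data.frame(compound_id = names(bmu), bmu = as.integer(bmu),
             label = unname(label[names(bmu)]), stringsAsFactors = FALSE)
}

#' Assign a train/test split to a dataset via a self-organizing map
#'
#' Convenience wrapper: trains a SOM on the dataset's descriptors, maps all
#' compounds, and applies [split_by_som()].
#'
#' @param dataset `qsar_dataset`.
#' @param test_size number of test compounds.
#' @param rows,cols,epochs passed to [train_som()].
#' @param seed seed for both map training and within-unit sampling.
#' @return the dataset with its `split` filled in; the split table is
#'   attached as attribute `"som_split"`.
#' @export
som_split_dataset <- function(dataset, test_size, rows = 6, cols = 6,
                              epochs = 500 * rows * cols, seed = 1) {
  stopifnot(inherits(dataset, "qsar_dataset"))
  grid <- train_som(dataset$X, rows, cols, epochs, seed)
  bmu <- map_to_bmu(grid, dataset$X)
  tab <- split_by_som(bmu, test_size, seed)
  out <- qsar_dataset(dataset$X, dataset$y, tab$label)
  attr(out, "som_split") <- tab
  out
}
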