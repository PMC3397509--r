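#' garf: genetic algorithm-random forest QSAR modeling
#'
#' Tools for descriptor-based QSAR regression: preprocessing filters,
#' self-organizing-map dataset splitting, genetic-algorithm descriptor
#' selection with random-forest out-of-bag error as the fitness, and the
#' Golbraikh-Tropsha / Roy external-validation battery with Y-randomization.
#'
#' @keywords internal
"_PACKAGE"

## ---- descriptor matrices -------------------------------------------------

#' Validate a descriptor matrix
#'
#' A descriptor matrix is a plain numeric matrix whose rownames are unique
#' compound identifiers and whose colnames are unique descriptor names, with
#' every cell finite. All higher-level functions in the package accept and
#' return matrices in this form.
#'
#' @param x numeric matrix with rownames (compound IDs) and colnames
#'   (descriptor names).
#' @return `x`, invisibly, after validation.
#' @export
validate_descriptor_matrix <- function(x) {
  if (!is.matrix(x) || !is.numeric(x))
    stop("descriptor matrix must be a numeric matrix", call. = FALSE)
  if (is.null(rownames(x)) || anyDuplicated(rownames(x)))
    stop("descriptor matrix needs unique compound IDs as rownames", call. = FALSE)
  if (is.null(colnames(x)) || anyDuplicated(colnames(x)))
    stop("descriptor matrix needs unique descriptor names as colnames", call. = FALSE)
  if (!all(is.finite(x))) {
    bad <- which(!is.finite(x), arr.ind = TRUE)[1, ]
    stop(sprintf("non-finite value at compound '%s', descriptor '%s'",
                 rownames(x)[bad[1]], colnames(x)[bad[2]]), call. = FALSE)
  }
  invisible(x)
}

#' Read a descriptor matrix from CSV
#'
#' Expects a header row; the first column (named `compound_id`) holds compound
#' identifiers, remaining columns hold numeric descriptor values. Duplicate
#' IDs and non-numeric cells are rejected with the offending row and column
#' named.
#'
#' @param path path to a CSV file.
#' @return numeric matrix, compounds in rows, descriptors in columns.
#' @export
read_descriptor_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, check.names = FALSE, colClasses = "character")
  if (ncol(df) < 2) stop("need an ID column plus at least one descriptor", call. = FALSE)
  ids <- df[[1]]
  dup <- ids[duplicated(ids)]
  if (length(dup))
    stop("duplicated compound ID(s): ", paste(unique(dup), collapse = ", "),
         call. = FALSE)
  vals <- as.matrix(df[, -1, drop = FALSE])
  num <- suppressWarnings(matrix(as.numeric(vals), nrow = nrow(vals),
                                 dimnames = list(ids, colnames(vals))))
  if (anyNA(num)) {
    bad <- which(is.na(num), arr.ind = TRUE)[1, ]
    stop(sprintf("unparseable cell at row '%s', column '%s' (value '%s')",
                 ids[bad[1]], colnames(num)[bad[2]], vals[bad[1], bad[2]]),
         call. = FALSE)
  }
  validate_descriptor_matrix(num)
  num
}

#' Write a descriptor matrix to CSV
#'
#' Inverse of [read_descriptor_csv()]; values printed with 15 significant
#' digits so that decimal text of up to 12 significant digits round-trips
#' exactly.
#'
#' @param x descriptor matrix.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_descriptor_csv <- function(x, path) {
  validate_descriptor_matrix(x)
  df <- data.frame(compound_id = rownames(x),
                   format(x, digits = 15, trim = TRUE, scientific = FALSE),
                   check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read an activity table from CSV
#'
#' Expects columns `compound_id,pic50`. Activities are pIC50 values
#' (-log10 of molar IC50).
#'
#' @param path path to a CSV file.
#' @return named numeric vector of pIC50 values.
#' @export
read_activity_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, colClasses = c("character", "character"))
  if (!all(c("compound_id", "pic50") %in% names(df)))
    stop("activity file needs columns 'compound_id' and 'pic50'", call. = FALSE)
  if (anyDuplicated(df$compound_id))
    stop("duplicated compound ID(s) in activity file", call. = FALSE)
  y <- suppressWarnings(as.numeric(df$pic50))
  if (anyNA(y) || !all(is.finite(y)))
    stop("non-numeric pic50 for compound '",
         df$compound_id[which(!is.finite(y))[1]], "'", call. = FALSE)
  stats::setNames(y, df$compound_id)
}

## ---- QSAR dataset --------------------------------------------------------

#' Assemble a QSAR dataset from descriptors and activities
#'
#' Inner-joins a descriptor matrix with an activity vector on compound ID.
#' Compounds present in only one of the two inputs are dropped with a warning;
#' an empty intersection is an error. The split starts out `"unassigned"`
#' for every compound (see [split_by_som()]).
#'
#' @param x descriptor matrix (see [validate_descriptor_matrix()]).
#' @param y named numeric vector of activities.
#' @return an object of class `qsar_dataset`: a list with elements `X`
#'   (matrix), `y` (named vector, same order) and `split` (factor with levels
#'   train/test/unassigned).
#' @export
assemble_dataset <- function(x, y) {
  validate_descriptor_matrix(x)
  if (is.null(names(y)) || anyDuplicated(names(y)))
    stop("activity vector needs unique compound names", call. = FALSE)
  common <- intersect(rownames(x), names(y))
  if (!length(common))
    stop("no compound IDs shared between descriptors and activities", call. = FALSE)
  dropped <- setdiff(union(rownames(x), names(y)), common)
  if (length(dropped))
    warning("dropped ", length(dropped), " compound(s) lacking descriptors or activity: ",
            paste(dropped, collapse = ", "), call. = FALSE)
  qsar_dataset(x[common, , drop = FALSE], y[common])
}

#' Construct a QSAR dataset
#'
#' @param X descriptor matrix.
#' @param y activity vector aligned with `rownames(X)`.
#' @param split optional factor/character of labels in train/test/unassigned.
#' @return `qsar_dataset` object.
#' @export
qsar_dataset <- function(X, y, split = NULL) {
  validate_descriptor_matrix(X)
  if (length(y) != nrow(X) || !identical(names(y), rownames(X)))
    stop("activities must cover the same compounds, in the same order, as X",
         call. = FALSE)
  if (!all(is.finite(y))) stop("activities must be finite", call. = FALSE)
  if (is.null(split)) split <- rep("unassigned", nrow(X))
  split <- factor(as.character(split), levels = c("train", "test", "unassigned"))
  if (anyNA(split) || length(split) != nrow(X))
    stop("split must be one of train/test/unassigned per compound", call. = FALSE)
  structure(list(X = X, y = y, split = split), class = "qsar_dataset")
}

#' @export
print.qsar_dataset <- function(x, ...) {
  cat(sprintf("QSAR dataset: %d compounds x %d descriptors (%d train / %d test / %d unassigned)\n",
              nrow(x$X), ncol(x$X), sum(x$split == "train"),
              sum(x$split == "test"), sum(x$split == "unassigned")))
  invisible(x)
}

#' Subset a QSAR dataset to one split
#'
#' @param dataset `qsar_dataset`.
#' @param which one of `"train"`, `"test"`, `"unassigned"`.
#' @return `qsar_dataset` restricted to the requested compounds.
#' @export
dataset_subset <- function(dataset, which = c("train", "test", "unassigned")) {
  which <- match.arg(which)
  keep <- dataset$split == which
  if (!any(keep)) stop("no compounds labelled '", which, "'", call. = FALSE)
  qsar_dataset(dataset$X[keep, , drop = FALSE], dataset$y[keep],
               dataset$split[keep])
}

## ---- packaged benchmark --------------------------------------------------

#' Load the packaged FBPase inhibitor benchmark
#'
#' A transcription of a published benchmark of 190 fructose
#' 1,6-bisphosphatase (FBPase) inhibitors: observed pIC50, the predictions of
#' a GA-RF model and of a full-descriptor RF model, and the train/test
#' membership used in that study (126 training, 64 test compounds). The
#' loader re-checks these invariants on every call and fails loudly on any
#' violation, which would indicate a transcription error.
#'
#' @return data.frame with columns `compound_no`, `observed`, `garf_pred`,
#'   `rf_pred`, `is_test` (logical), `source`.
#' @export
load_table3_fixture <- function() {
  path <- system.file("extdata", "table3_fbpase.csv", package = "garf",
                      mustWork = TRUE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  df$is_test <- as.logical(df$is_test)
  stopifnot(
    nrow(df) == 190,
    identical(df$compound_no, 1:190),
    sum(df$is_test) == 64,
    all(df$observed >= 3.60 & df$observed <= 8.00),
    all(is.finite(df$garf_pred)), all(is.finite(df$rf_pred))
  )
  df
}
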