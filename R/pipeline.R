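## End-to-end GA-RF pipeline: preprocess -> SOM split -> GA descriptor
## selection -> final forest -> validation battery (-> optional
## Y-randomization). Stages never mutate their inputs; the returned manifest
## records configuration, per-stage descriptor counts, and every artifact.

#' Run the full GA-RF modeling pipeline
#'
#' @param X descriptor matrix.
#' @param y named activity vector.
#' @param test_size number of test compounds for the SOM split.
#' @param zero_fraction,freq_ratio_cutoff,unique_percent_cutoff,corr_cutoff
#'   preprocessing thresholds (see [preprocess_pipeline()]).
#' @param som_rows,som_cols,som_epochs SOM shape and training length.
#' @param ga GA configuration from [ga_config()].
#' @param final_ntree trees in the final refit (default 500).
#' @param yrand_rounds Y-randomization rounds; 0 skips the check.
#' @param seed master seed for the SOM split, final forest and
#'   Y-randomization (the GA uses `ga$ga_seed`).
#' @param verbose print per-stage counts.
#' @return object of class `garf_run`: list with `config`, `counts`
#'   (descriptor counts per stage), `filter_report`, `dataset` (with split),
#'   `ga` (`ga_result`), `model` (`forest_model`), `report`
#'   (`validation_report`), and `yrand` (`yrand_result` or NULL).
#' @export
run_pipeline <- function(X, y, test_size,
                         zero_fraction = 0.85, freq_ratio_cutoff = 19,
                         unique_percent_cutoff = 10, corr_cutoff = 0.75,
                         som_rows = 6, som_cols = 6,
                         som_epochs = 500 * som_rows * som_cols,
                         ga = ga_config(), final_ntree = 500,
                         yrand_rounds = 0, seed = 1, verbose = FALSE) {
  pre <- preprocess_pipeline(X, zero_fraction, freq_ratio_cutoff,
                             unique_percent_cutoff, corr_cutoff,
                             verbose = verbose)
  dataset <- assemble_dataset(pre$matrix, y)
  dataset <- som_split_dataset(dataset, test_size, som_rows, som_cols,
                               som_epochs, seed)
  ga_res <- run_ga(dataset, ga)
  mask <- ga_res$best_mask
  proc <- rf_procedure(ntree = final_ntree, mask = mask, seed = seed)
  report <- proc(dataset)
  tr <- dataset$split == "train"
  model <- fit_forest(dataset$X[tr, mask == 1, drop = FALSE],
                      dataset$y[tr], ntree = final_ntree, seed = seed)
  yrand <- NULL
  if (yrand_rounds > 0)
    yrand <- y_randomization(dataset, proc, rounds = yrand_rounds, seed = seed)
  counts <- c(input = ncol(X), filtered = ncol(pre$matrix),
              selected = sum(mask))
  if (verbose)
    message(sprintf("descriptors: %d input -> %d filtered -> %d GA-selected",
                    counts["input"], counts["filtered"], counts["selected"]))
  structure(list(config = list(test_size = test_size, seed = seed, ga = ga,
                               final_ntree = final_ntree,
                               corr_cutoff = corr_cutoff,
                               zero_fraction = zero_fraction),
                 counts = counts, filter_report = pre$report,
                 dataset = dataset, ga = ga_res, model = model,
                 report = report, yrand = yrand),
            class = "garf_run")
}

#' @export
print.garf_run <- function(x, ...) {
  cat(sprintf("GA-RF run: %d -> %d -> %d descriptors; ",
              x$counts["input"], x$counts["filtered"], x$counts["selected"]))
  cat(sprintf("best OOB MSE %.4f\n", x$ga$best_fitness))
  print(x$report)
  invisible(x)
}
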