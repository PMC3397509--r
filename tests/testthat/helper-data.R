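# small deterministic matrices used across tests

make_matrix <- function(vals, n, ids = NULL, cols = NULL) {
  m <- matrix(vals, nrow = n)
  rownames(m) <- ids %||% sprintf("c%02d", seq_len(nrow(m)))
  colnames(m) <- cols %||% sprintf("D%03d", seq_len(ncol(m)))
  m
}

`%||%` <- function(a, b) if (is.null(a)) b else a

random_matrix <- function(n, p, seed = 1) {
  withr::with_seed(seed, make_matrix(rnorm(n * p), n))
}

# a small signal-bearing dataset with train/test labels
small_signal_dataset <- function(n = 80, p = 15, n_inf = 4, seed = 1,
                                 n_test = 25) {
  g <- generate_qsar(synth_spec(n_compounds = n, n_descriptors = p,
                                n_informative = n_inf,
                                beta = rep(1, n_inf),
                                noise_sd = 0.7, seed = seed))
  split <- rep("train", n)
  split[withr::with_seed(seed, sample(n, n_test))] <- "test"
  list(dataset = qsar_dataset(g$dataset$X, g$dataset$y, split),
       truth = g$truth)
}
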