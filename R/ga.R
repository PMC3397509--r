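## Binary genetic algorithm over descriptor subsets. Chromosomes are 0/1
## masks over the descriptor columns; the fitness to MINIMIZE is the
## out-of-bag MSE of a random forest fit on the masked training descriptors.
## Selection is linear ranking (selective pressure 2) realized by stochastic
## universal sampling; variation is double-point crossover plus bit-flip
## mutation; reinsertion is elitist (offspring replace the worst).
##
## Fitness seeds are derived from a hash of the mask, so the fitness is a
## deterministic function of the mask and the GA is not misled by forest
## sampling noise between identical masks. Evaluations are memoized.

#' GA configuration
#'
#' Defaults follow the conventional evolutionary-toolbox settings for binary
#' descriptor selection: 50 individuals, 200 generations, stochastic
#' universal sampling with a generation gap of 0.9 (45 offspring), double
#' point crossover at probability 0.7, and a mutation rate of 0.7/p.
#'
#' @param population_size number of individuals.
#' @param max_generations fixed number of generations (sole termination rule).
#' @param generation_gap fraction of the population replaced by offspring.
#' @param crossover_prob probability of performing crossover per pair.
#' @param mutation_rate per-bit flip probability; `NULL` means 0.7/p.
#' @param rf_ntree trees per fitness evaluation (100 suffices for ranking
#'   masks; the final model is refit at full size).
#' @param ga_seed master seed for the whole run.
#' @return list of class `ga_config`.
#' @export
ga_config <- function(population_size = 50, max_generations = 200,
                      generation_gap = 0.9, crossover_prob = 0.7,
                      mutation_rate = NULL, rf_ntree = 100, ga_seed = 1) {
  stopifnot(population_size > 0, max_generations > 0,
            generation_gap > 0, generation_gap <= 1,
            crossover_prob >= 0, crossover_prob <= 1,
            is.null(mutation_rate) ||
              (mutation_rate >= 0 && mutation_rate <= 1))
  structure(list(population_size = as.integer(population_size),
                 max_generations = as.integer(max_generations),
                 generation_gap = generation_gap,
                 crossover_prob = crossover_prob,
                 mutation_rate = mutation_rate,
                 rf_ntree = as.integer(rf_ntree),
                 ga_seed = as.integer(ga_seed)),
            class = "ga_config")
}

# set one random bit in an all-zero mask (non-empty invariant)
repair_mask <- function(mask) {
  if (!any(mask)) mask[sample.int(length(mask), 1)] <- 1L
  mask
}

#' Initialize a GA population
#'
#' Each bit is i.i.d. Bernoulli(0.5); an all-zero chromosome gets one
#' uniformly random bit set. Draws from the current RNG state (seed it, or
#' rely on [run_ga()] which seeds the whole run).
#'
#' @param p chromosome length (number of descriptors).
#' @param size population size.
#' @return integer 0/1 matrix, one chromosome per row.
#' @export
init_population <- function(p, size) {
  stopifnot(p >= 1, size > 0)
  pop <- matrix(sample(0:1, p * size, replace = TRUE), nrow = size)
  t(apply(pop, 1, repair_mask))
}

# polynomial hash of the mask bits, < 2^31, mixed with the master seed
mask_seed <- function(mask, ga_seed) {
  h <- 0
  for (b in mask) h <- (h * 31 + b + 1) %% 2147483647
  as.integer((h + ga_seed) %% 2147483647)
}

#' Fitness of a descriptor mask
#'
#' Out-of-bag MSE of a random forest fit on the masked descriptor columns of
#' the training-split compounds. The forest seed is derived from the mask
#' hash and the master seed, making the fitness a deterministic function of
#' the mask; evaluations are memoized in `cache` when supplied.
#'
#' @param mask integer 0/1 vector over the dataset's descriptors.
#' @param dataset `qsar_dataset` with a train split assigned.
#' @param rf_ntree trees per evaluation.
#' @param ga_seed master seed for derived forest seeds.
#' @param cache optional environment used for memoization.
#' @return OOB MSE (lower is fitter).
#' @export
ga_fitness <- function(mask, dataset, rf_ntree = 100, ga_seed = 1,
                       cache = NULL) {
  if (!any(mask == 1)) stop("empty descriptor mask", call. = FALSE)
  key <- paste(mask, collapse = "")
  if (!is.null(cache) && !is.null(cache[[key]])) return(cache[[key]])
  tr <- dataset$split == "train"
  if (!any(tr)) stop("dataset has no training compounds", call. = FALSE)
  X <- dataset$X[tr, mask == 1, drop = FALSE]
  m <- fit_forest(X, dataset$y[tr], ntree = rf_ntree,
                  mtry = default_mtry(ncol(X)),
                  seed = mask_seed(mask, ga_seed))
  val <- oob_mse(m)
  if (!is.null(cache)) cache[[key]] <- val
  val
}

#' Select parents by linear ranking + stochastic universal sampling
#'
#' Fitnesses (to minimize) are converted to selection expectations by linear
#' ranking with selective pressure 2: the best individual expects 2 copies
#' per `size` slots, the worst 0, with tied fitnesses sharing averaged ranks
#' (so identical fitnesses yield uniform selection). SUS then places
#' `n_offspring` equally spaced pointers on the cumulative expectation
#' wheel, guaranteeing each individual a count within one of its
#' expectation. The returned index list is shuffled for pairing.
#'
#' @param fitnesses numeric vector (lower = better).
#' @param n_offspring number of parents to draw.
#' @return integer vector of selected indices, length `n_offspring`.
#' @export
select_parents <- function(fitnesses, n_offspring) {
  n <- length(fitnesses)
  stopifnot(n >= 1, n_offspring >= 1)
  if (n == 1) return(rep(1L, n_offspring))
  pos <- rank(fitnesses, ties.method = "average")  # 1 = best (min)
  expect <- 2 * (n - pos) / (n - 1)                # sums to n
  cum <- cumsum(expect)
  spacing <- cum[n] / n_offspring
  pointers <- stats::runif(1, 0, spacing) + (seq_len(n_offspring) - 1) * spacing
  idx <- vapply(pointers, function(ptr) which(cum >= ptr)[1], integer(1))
  if (length(idx) == 1) return(idx)
  sample(idx)  # shuffle for random pairing
}

#' Double-point crossover
#'
#' With probability `prob`, two cut points `1 <= c1 < c2 <= p-1` are chosen
#' uniformly and the bit segment strictly after `c1` up to `c2` is exchanged
#' between the parents; otherwise the parents are returned unchanged. Any
#' all-zero child is repaired by setting one random bit.
#'
#' @param a,b parent chromosomes (equal-length 0/1 vectors).
#' @param prob crossover probability.
#' @param cuts optional fixed `c(c1, c2)` (forces crossover; used in tests).
#' @return list of two children.
#' @export
double_point_crossover <- function(a, b, prob = 0.7, cuts = NULL) {
  if (length(a) != length(b)) stop("chromosome length mismatch", call. = FALSE)
  p <- length(a)
  do_cross <- !is.null(cuts) || (p >= 3 && stats::runif(1) < prob)
  if (do_cross) {
    if (is.null(cuts)) cuts <- sort(sample.int(p - 1, 2))
    seg <- (cuts[1] + 1):cuts[2]
    tmp <- a[seg]; a[seg] <- b[seg]; b[seg] <- tmp
  }
  list(repair_mask(a), repair_mask(b))
}

#' Bit-flip mutation
#'
#' Each bit flips independently with probability `rate`; an all-zero result
#' is repaired by setting one random bit.
#'
#' @param mask chromosome.
#' @param rate per-bit flip probability.
#' @return mutated chromosome.
#' @export
mutate_mask <- function(mask, rate) {
  stopifnot(rate >= 0, rate <= 1)
  flip <- stats::runif(length(mask)) < rate
  repair_mask(ifelse(flip, 1L - mask, mask))
}

#' Elitist reinsertion
#'
#' Offspring replace the worst-fitness members of the old population; the
#' `population - offspring` best old members survive. Fitness ties among old
#' members are broken in favour of the earlier (older) individual.
#'
#' @param old_pop,old_fit old population matrix and fitnesses.
#' @param off_pop,off_fit offspring matrix and fitnesses.
#' @return list with `pop` and `fit` of the new population.
#' @export
reinsert <- function(old_pop, old_fit, off_pop, off_fit) {
  n <- nrow(old_pop); k <- nrow(off_pop)
  if (k > n) stop("more offspring than population slots", call. = FALSE)
  keep <- order(old_fit)[seq_len(n - k)]  # order() is stable: older wins ties
  list(pop = rbind(old_pop[keep, , drop = FALSE], off_pop),
       fit = c(old_fit[keep], off_fit))
}

#' Run the genetic algorithm for descriptor selection
#'
#' Loops select -> crossover -> mutate -> evaluate -> reinsert for a fixed
#' number of generations, minimizing random-forest OOB MSE on the training
#' split. Deterministic for a fixed `ga_seed`: the best-ever fitness is
#' monotone non-increasing and the whole result is bit-identical on rerun.
#'
#' @param dataset `qsar_dataset` with a train split assigned (descriptors
#'   should already be preprocessed).
#' @param config `ga_config`.
#' @return object of class `ga_result`: list with `best_mask` (named 0/1
#'   vector), `best_fitness`, `history` (per-generation best/mean fitness),
#'   `evaluations` (forest fits performed), `cache_hits`.
#' @export
run_ga <- function(dataset, config = ga_config()) {
  stopifnot(inherits(dataset, "qsar_dataset"), inherits(config, "ga_config"))
  if (!any(dataset$split == "train"))
    stop("dataset has no training compounds", call. = FALSE)
  p <- ncol(dataset$X)
  rate <- if (is.null(config$mutation_rate)) 0.7 / p else config$mutation_rate
  n_off <- round(config$generation_gap * config$population_size)
  cache <- new.env(parent = emptyenv())
  evals <- 0L; hits <- 0L
  eval_mask <- function(mask) {
    key <- paste(mask, collapse = "")
    if (!is.null(cache[[key]])) { hits <<- hits + 1L; return(cache[[key]]) }
    evals <<- evals + 1L
    ga_fitness(mask, dataset, config$rf_ntree, config$ga_seed, cache)
  }
  withr::with_seed(config$ga_seed, {
    pop <- init_population(p, config$population_size)
    fit <- apply(pop, 1, eval_mask)
    best_i <- which.min(fit)
    best_mask <- pop[best_i, ]; best_fit <- fit[best_i]
    history <- data.frame(generation = integer(), best = numeric(),
                          mean = numeric())
    for (g in seq_len(config$max_generations)) {
      parents <- select_parents(fit, n_off)
      off <- matrix(0L, n_off, p)
      i <- 1
      while (i <= n_off) {
        a <- pop[parents[i], ]
        b <- pop[parents[if (i < n_off) i + 1 else 1], ]
        ch <- double_point_crossover(a, b, config$crossover_prob)
        off[i, ] <- mutate_mask(ch[[1]], rate)
        if (i + 1 <= n_off) off[i + 1, ] <- mutate_mask(ch[[2]], rate)
        i <- i + 2
      }
      off_fit <- apply(off, 1, eval_mask)
      res <- reinsert(pop, fit, off, off_fit)
      pop <- res$pop; fit <- res$fit
      gi <- which.min(fit)
      if (fit[gi] < best_fit) { best_fit <- fit[gi]; best_mask <- pop[gi, ] }
      history <- rbind(history,
                       data.frame(generation = g, best = best_fit,
                                  mean = mean(fit)))
    }
    structure(list(best_mask = stats::setNames(best_mask, colnames(dataset$X)),
                   best_fitness = best_fit, history = history,
                   evaluations = evals, cache_hits = hits,
                   config = config),
              class = "ga_result")
  })
}

#' @export
print.ga_result <- function(x, ...) {
  cat(sprintf("GA result: %d/%d descriptors selected, best OOB MSE = %.4f (%d evaluations, %d cache hits)\n",
              sum(x$best_mask), length(x$best_mask), x$best_fitness,
              x$evaluations, x$cache_hits))
  invisible(x)
}
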