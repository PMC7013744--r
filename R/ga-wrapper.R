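#' Genetic algorithm parameters
#'
#' Defaults mirror the full-scale selection runs: population 500,
#' 500 generations, two-point crossover with probability 0.65, bit
#' mutation rate 0.03, roulette-wheel selection and elitism of one.
#' `cardinality` optionally constrains every chromosome to exactly `k`
#' selected features via the repair operator.
#'
#' @param population_size Number of chromosomes per generation.
#' @param generations Number of generations (the stopping criterion).
#' @param crossover_probability Probability that a mated pair exchanges a
#'   two-point segment.
#' @param mutation_rate Independent per-bit flip probability.
#' @param cardinality Optional exact number of selected features.
#' @param elitism Number of best chromosomes copied unchanged.
#' @param selection_scaling `"window"` (default) rebases fitness to the
#'   current population minimum before the roulette draw, restoring
#'   selection pressure when all fitness values sit in a narrow band far
#'   from zero (as the accuracy-sum fitness does); `"raw"` uses the
#'   fitness values as they are.
#' @param rng_seed Seed driving every stochastic step of the run.
#' @return Object of class `ga_params`.
#' @export
ga_params <- function(population_size = 500L, generations = 500L,
                      crossover_probability = 0.65, mutation_rate = 0.03,
                      cardinality = NULL, elitism = 1L,
                      selection_scaling = c("window", "raw"),
                      rng_seed = 1L) {
  selection_scaling <- match.arg(selection_scaling)
  stopifnot(
    population_size >= 2, generations >= 1,
    crossover_probability >= 0, crossover_probability <= 1,
    mutation_rate >= 0, mutation_rate <= 1,
    elitism >= 0, elitism < population_size
  )
  structure(list(
    population_size = as.integer(population_size),
    generations = as.integer(generations),
    crossover_probability = crossover_probability,
    mutation_rate = mutation_rate,
    cardinality = if (!is.null(cardinality)) as.integer(cardinality),
    elitism = as.integer(elitism),
    selection_scaling = selection_scaling,
    rng_seed = as.integer(rng_seed)
  ), class = "ga_params")
}

#' Standardize feature columns of a labeled table
#'
#' Per-feature z-transform `(x - mean) / sd` with the sample standard
#' deviation, bringing all features onto a comparable numeric scale so no
#' attribute dominates the kernel distance.  Constant (zero-variance)
#' features map to 0 and are flagged.  The learned means and SDs can be
#' reapplied to held-out data with [apply_scaling()].
#'
#' @param table Labeled feature table.
#' @param features Feature columns to scale; defaults to all `F*`
#'   columns.
#' @return Object of class `scaled_table`: list with `table` (scaled
#'   data), `center`, `scale` and `degenerate` (named logical).
#' @export
scale_features <- function(table, features = NULL) {
  if (is.null(features)) features <- feature_columns(table)
  center <- vapply(features, function(f) mean(table[[f]]), numeric(1))
  sds <- vapply(features, function(f) stats::sd(table[[f]]), numeric(1))
  degenerate <- sds < 1e-12
  out <- table
  for (i in seq_along(features)) {
    f <- features[i]
    out[[f]] <- if (degenerate[i]) rep(0, nrow(table)) else
      (table[[f]] - center[i]) / sds[i]
  }
  structure(list(table = out, center = center, scale = sds,
                 degenerate = degenerate, features = features),
            class = "scaled_table")
}

#' @rdname scale_features
#' @param scaling A `scaled_table` whose parameters are reapplied.
#' @export
apply_scaling <- function(table, scaling) {
  out <- table
  for (i in seq_along(scaling$features)) {
    f <- scaling$features[i]
    out[[f]] <- if (scaling$degenerate[i]) rep(0, nrow(table)) else
      (table[[f]] - scaling$center[i]) / scaling$scale[i]
  }
  out
}

#' Cross-setting fitness of a set of per-setting accuracies
#'
#' The sum of the per-setting classification accuracies minus the sum of
#' all pairwise squared accuracy differences.  For a fixed accuracy
#' total, the penalty vanishes exactly when all settings agree, so the
#' fitness rewards subsets that are both accurate and consistent across
#' acquisition settings.
#'
#' @param accuracies Numeric vector of per-setting accuracies in
#'   `[0, 1]`.
#' @return A single numeric fitness value.
#' @examples
#' ga_fitness(c(0.9, 0.9, 0.9, 0.9)) # 3.6
#' ga_fitness(c(1.0, 0.9))           # 1.89
#' @export
ga_fitness <- function(accuracies) {
  if (length(accuracies) < 1 || any(!is.finite(accuracies)) ||
      any(accuracies < 0 | accuracies > 1)) {
    stop_invalid("accuracies must all lie in [0, 1]")
  }
  penalty <- sum(outer(accuracies, accuracies, "-")^2) / 2
  sum(accuracies) - penalty
}

# Canonical cache key of a chromosome.
bits_key <- function(bits) paste(bits, collapse = "")

#' Evaluate one chromosome on every setting
#'
#' For each acquisition setting, the features selected by the chromosome
#' are scored by stratified 5-fold cross-validated SVM accuracy; the
#' per-setting accuracies are combined by [ga_fitness()].  Results can be
#' cached (keyed by bit pattern) so duplicated chromosomes are evaluated
#' once.
#'
#' @param bits Integer 0/1 vector over the candidate pool.
#' @param setting_data Named list, one element per setting, each a list
#'   with `x` (feature matrix over the pool columns) and `y` (two-level
#'   factor).
#' @param config An [svm_config()].
#' @param cache Optional environment used as a fitness cache.
#' @return Object of class `fitness_report`: list with `accuracies`,
#'   `fitness` and `bits`.
#' @export
evaluate_chromosome <- function(bits, setting_data, config = svm_config(),
                                cache = NULL) {
  if (sum(bits) < 1) stop_invalid("chromosome selects no features")
  key <- bits_key(bits)
  if (!is.null(cache) && !is.null(cache[[key]])) return(cache[[key]])
  sel <- which(bits == 1)
  acc <- vapply(setting_data, function(d) {
    svm_cross_validate(d$x[, sel, drop = FALSE], d$y, config)$mean_accuracy
  }, numeric(1))
  rep <- structure(list(accuracies = acc, fitness = ga_fitness(acc),
                        bits = bits),
                   class = "fitness_report")
  if (!is.null(cache)) cache[[key]] <- rep
  rep
}

#' Roulette-wheel selection
#'
#' Samples chromosome indices with replacement, with probability
#' proportional to fitness.  If any fitness is negative the values are
#' shifted so the minimum is zero (plus a small epsilon); if all values
#' are equal (including all zero) sampling is uniform.  Uses the current
#' RNG stream.
#'
#' @param fitness Numeric vector of fitness values.
#' @param n Number of draws.
#' @return Integer vector of selected indices.
#' @export
roulette_select <- function(fitness, n) {
  f <- fitness
  if (any(f < 0)) f <- f - min(f) + 1e-12
  if (sum(f) <= 0) f <- rep(1, length(f))
  sample.int(length(f), n, replace = TRUE, prob = f / sum(f))
}

#' Two-point crossover
#'
#' With probability `pc`, two distinct cut points are drawn uniformly and
#' the segment between them is exchanged between the parents; otherwise
#' the parents are returned unchanged.  Uses the current RNG stream.
#'
#' @param a,b Integer 0/1 vectors of equal length (at least 3).
#' @param pc Crossover probability.
#' @return List of the two children.
#' @export
two_point_crossover <- function(a, b, pc) {
  stopifnot(length(a) == length(b), length(a) >= 3)
  if (stats::runif(1) < pc) {
    cuts <- sort(resample(seq_len(length(a) - 1L), 2))
    seg <- (cuts[1] + 1L):cuts[2]
    tmp <- a[seg]
    a[seg] <- b[seg]
    b[seg] <- tmp
  }
  list(a, b)
}

#' Bitwise mutation
#'
#' Each bit flips independently with probability `rate`.  Uses the
#' current RNG stream.
#'
#' @param bits Integer 0/1 vector.
#' @param rate Per-bit flip probability in `[0, 1]`.
#' @return Mutated 0/1 vector.
#' @export
mutate_bits <- function(bits, rate) {
  stopifnot(rate >= 0, rate <= 1)
  flip <- stats::runif(length(bits)) < rate
  ifelse(flip, 1L - bits, bits)
}

#' Cardinality repair
#'
#' Forces a chromosome to exactly `k` selected features: excess ones are
#' cleared and missing ones added, at uniformly random positions.  A
#' chromosome already satisfying the constraint is returned unchanged.
#'
#' @param bits Integer 0/1 vector.
#' @param k Required number of set bits (`k <= length(bits)`).
#' @return Repaired 0/1 vector with exactly `k` ones.
#' @export
repair_bits <- function(bits, k) {
  stopifnot(k >= 1, k <= length(bits))
  ones <- which(bits == 1)
  if (length(ones) > k) {
    bits[resample(ones, length(ones) - k)] <- 0L
  } else if (length(ones) < k) {
    zeros <- which(bits == 0)
    bits[resample(zeros, k - length(ones))] <- 1L
  }
  bits
}

# One random chromosome of length f (exactly k ones when k is set).
random_chromosome <- function(f, k = NULL) {
  if (is.null(k)) {
    bits <- as.integer(stats::runif(f) < 0.5)
    if (sum(bits) == 0) bits[resample(seq_len(f), 1)] <- 1L
    bits
  } else {
    bits <- integer(f)
    bits[resample(seq_len(f), k)] <- 1L
    bits
  }
}

#' Evolve a feature subset with the genetic algorithm
#'
#' Generational GA over binary chromosomes on the candidate pool:
#' roulette-wheel selection, two-point crossover, bitwise mutation,
#' optional exact-cardinality repair, elitism, and the cross-setting
#' SVM fitness of [evaluate_chromosome()].  All randomness (population
#' initialization, selection, crossover, mutation, repair) is driven by
#' `params$rng_seed`; fold assignment is fixed by the classifier
#' config's `fold_seed`, so two runs with identical inputs and seeds are
#' identical.
#'
#' @param setting_data Named list of per-setting `list(x, y)` training
#'   data over the pool columns (see [evaluate_chromosome()]).
#' @param params A [ga_params()].
#' @param config An [svm_config()].
#' @return Object of class `ga_result`: list with `best_bits`,
#'   `best_features` (column names), `best_report`, `history`
#'   (data.frame of per-generation best/mean fitness), `params`, and
#'   `n_evaluations` (unique chromosomes evaluated).
#' @export
ga_evolve <- function(setting_data, params = ga_params(),
                      config = svm_config()) {
  f <- ncol(setting_data[[1]]$x)
  if (is.null(f) || f < 1) stop_invalid("empty candidate pool")
  k <- params$cardinality
  cache <- new.env(parent = emptyenv())

  with_seed(params$rng_seed, {
    pop <- replicate(params$population_size, random_chromosome(f, k),
                     simplify = FALSE)
    reports <- lapply(pop, evaluate_chromosome, setting_data, config, cache)
    fit <- vapply(reports, `[[`, numeric(1), "fitness")
    best_idx <- which.max(fit)
    best_report <- reports[[best_idx]]
    history <- data.frame(generation = 0L, best_fitness = max(fit),
                          mean_fitness = mean(fit))

    for (gen in seq_len(params$generations)) {
      elite_idx <- order(-fit)[seq_len(params$elitism)]
      n_children <- params$population_size - params$elitism
      children <- vector("list", n_children)
      i <- 1L
      sel_fit <- if (params$selection_scaling == "window")
        fit - min(fit) else fit
      while (i <= n_children) {
        parents <- roulette_select(sel_fit, 2)
        pair <- two_point_crossover(pop[[parents[1]]], pop[[parents[2]]],
                                    params$crossover_probability)
        for (child in pair) {
          if (i > n_children) break
          child <- mutate_bits(child, params$mutation_rate)
          child <- if (!is.null(k)) repair_bits(child, k) else {
            if (sum(child) == 0) child[resample(seq_len(f), 1)] <- 1L
            child
          }
          children[[i]] <- child
          i <- i + 1L
        }
      }
      pop <- c(pop[elite_idx], children)
      reports <- lapply(pop, evaluate_chromosome, setting_data, config,
                        cache)
      fit <- vapply(reports, `[[`, numeric(1), "fitness")
      gen_best <- which.max(fit)
      if (fit[gen_best] > best_report$fitness) {
        best_report <- reports[[gen_best]]
      }
      history <- rbind(history,
                       data.frame(generation = gen, best_fitness = max(fit),
                                  mean_fitness = mean(fit)))
    }
  })

  cols <- colnames(setting_data[[1]]$x)
  structure(list(
    best_bits = best_report$bits,
    best_features = if (!is.null(cols)) cols[best_report$bits == 1] else
      which(best_report$bits == 1),
    best_report = best_report,
    history = history,
    params = params,
    n_evaluations = length(ls(cache))
  ), class = "ga_result")
}

#' @export
print.ga_result <- function(x, ...) {
  cat("GA feature selection:", sum(x$best_bits), "features,",
      "fitness", format(x$best_report$fitness, digits = 6), "\n")
  cat(" selected:", paste(x$best_features, collapse = ", "), "\n")
  cat(" per-setting CV accuracy:",
      paste(format(x$best_report$accuracies, digits = 4), collapse = ", "),
      "\n")
  invisible(x)
}
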