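# Small per-setting training sets over a planted table, shared by the
# evaluation tests.
ga_setting_data <- function(tab, features) {
  settings <- sort(unique(tab$setting_id))
  setNames(lapply(settings, function(s) {
    rows <- tab$setting_id == s
    list(x = as.matrix(tab[rows, features, drop = FALSE]),
         y = factor(tab$class[rows]))
  }), paste0("setting_", settings))
}

test_that("fitness matches hand arithmetic and validates inputs", {
  expect_equal(ga_fitness(rep(0.9, 4)), 3.6)
  expect_equal(ga_fitness(c(1.0, 0.9)), 1.89, tolerance = 1e-12)
  expect_equal(ga_fitness(c(0.9835, 0.9886, 0.9827, 0.9581)), 3.9106580,
               tolerance = 1e-7)
  expect_error(ga_fitness(c(0.5, 1.2)), "\\[0, 1\\]")
  expect_error(ga_fitness(numeric(0)), "\\[0, 1\\]")
})

test_that("fitness rewards consistency at fixed total accuracy", {
  expect_equal(ga_fitness(c(0.8, 0.9, 0.7)), ga_fitness(c(0.7, 0.8, 0.9)))
  # equal split maximizes fitness for a fixed sum
  expect_gt(ga_fitness(rep(0.8, 4)), ga_fitness(c(0.95, 0.75, 0.8, 0.7)))
  expect_equal(ga_fitness(rep(0.8, 4)), sum(rep(0.8, 4)))
  expect_lt(ga_fitness(c(1, 0.6)), 1.6)
})

test_that("feature scaling centers, flags constants, and reapplies", {
  tab <- data.frame(sample_id = letters[1:3], setting_id = 1, pair_id = 1:3,
                    class = c("A", "B", "A"), F1 = c(1, 2, 3), F2 = rep(5, 3))
  sc <- scale_features(tab)
  expect_equal(sc$table$F1, c(-1, 0, 1))
  expect_equal(sc$table$F2, c(0, 0, 0))
  expect_true(sc$degenerate["F2"])
  # reapplication uses the learned parameters
  new <- tab; new$F1 <- c(4, 2, 0)
  expect_equal(apply_scaling(new, sc)$F1, c(2, 0, -2))
  tab2 <- planted_table(seed = 2, n = 10, n_features = 4)
  sc2 <- scale_features(tab2)
  for (f in paste0("F", 1:4)) {
    expect_equal(mean(sc2$table[[f]]), 0, tolerance = 1e-12)
    expect_equal(sd(sc2$table[[f]]), 1, tolerance = 1e-12)
  }
})

test_that("roulette selection is proportional and handles edge cases", {
  set.seed(5)
  draws <- roulette_select(c(3, 1), 10000)
  expect_lt(abs(mean(draws == 1) - 0.75), 3 * sqrt(0.75 * 0.25 / 10000))
  expect_equal(unique(roulette_select(5, 50)), 1L)
  set.seed(6)
  u <- roulette_select(c(0, 0, 0), 9000)
  expect_true(all(abs(table(u) / 9000 - 1 / 3) < 0.02))
  # negative fitness: shifted, still usable
  set.seed(7)
  expect_true(all(roulette_select(c(-2, -1, 3), 100) %in% 1:3))
})

test_that("two-point crossover swaps exactly the interior segment", {
  a <- rep(1L, 5); b <- rep(0L, 5)
  set.seed(1)
  found <- FALSE
  for (i in 1:50) {
    ch <- two_point_crossover(a, b, pc = 1)
    expect_equal(ch[[1]] + ch[[2]], rep(1L, 5))  # bits come from one parent
    if (identical(ch[[1]], c(1L, 0L, 0L, 1L, 1L))) found <- TRUE
  }
  expect_true(found)  # cuts after positions 1 and 3 occur
  expect_identical(two_point_crossover(a, b, pc = 0), list(a, b))
})

test_that("mutation flips at the configured rate", {
  bits <- rep(0L, 1000)
  expect_identical(mutate_bits(bits, 0), bits)
  expect_identical(mutate_bits(bits, 1), rep(1L, 1000))
  set.seed(2)
  flips <- replicate(20, sum(mutate_bits(bits, 0.03)))
  expect_lt(abs(mean(flips) - 30), 3 * sqrt(1000 * 0.03 * 0.97 / 20))
})

test_that("repair enforces exact cardinality idempotently", {
  set.seed(3)
  expect_identical(repair_bits(c(1L, 0L, 1L, 0L), 2), c(1L, 0L, 1L, 0L))
  expect_equal(sum(repair_bits(rep(1L, 10), 5)), 5)
  expect_equal(sum(repair_bits(rep(0L, 10), 4)), 4)
  for (i in 1:20) {
    bits <- as.integer(runif(15) < 0.5)
    expect_equal(sum(repair_bits(bits, 6)), 6)
  }
})

test_that("chromosome evaluation caches and reproduces fitness from stored accuracies", {
  tab <- planted_table(seed = 4, n = 30, n_features = 6, universal = 1:2,
                       settings = 2)
  sdata <- ga_setting_data(scale_features(tab)$table, paste0("F", 1:6))
  cache <- new.env()
  bits <- c(1L, 1L, 0L, 0L, 0L, 0L)
  r1 <- evaluate_chromosome(bits, sdata, svm_config(fold_seed = 1), cache)
  r2 <- evaluate_chromosome(bits, sdata, svm_config(fold_seed = 1), cache)
  expect_identical(r1, r2)
  expect_equal(r1$fitness, ga_fitness(r1$accuracies))
  expect_true(all(r1$accuracies >= 0.8))  # planted features classify well
  expect_error(evaluate_chromosome(rep(0L, 6), sdata), "no features")
  # noise-only chromosome sits near chance
  rn <- evaluate_chromosome(c(0L, 0L, 0L, 1L, 1L, 1L), sdata,
                            svm_config(fold_seed = 1))
  expect_lt(abs(mean(rn$accuracies) - 0.5), 0.15)
})

test_that("evolution is deterministic, monotone, and recovers planted subsets", {
  tab <- planted_table(seed = 8, n = 50, n_features = 10, universal = 1:2)
  sdata <- ga_setting_data(scale_features(tab)$table, paste0("F", 1:10))
  params <- ga_params(population_size = 16, generations = 10,
                      cardinality = 2, rng_seed = 7)
  cfg <- svm_config(fold_seed = 2)
  res <- ga_evolve(sdata, params, cfg)
  res2 <- ga_evolve(sdata, params, cfg)
  expect_identical(res$history, res2$history)
  expect_identical(res$best_bits, res2$best_bits)
  expect_true(all(diff(res$history$best_fitness) >= 0))
  expect_setequal(res$best_features, c("F1", "F2"))
  # the planted pair is the true optimum of this landscape
  planted <- evaluate_chromosome(c(1L, 1L, rep(0L, 8)), sdata, cfg)
  expect_gte(res$best_report$fitness, planted$fitness)
  expect_equal(res$best_report$fitness,
               ga_fitness(res$best_report$accuracies))
  expect_lte(res$n_evaluations, choose(10, 2))
})
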