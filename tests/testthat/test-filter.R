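test_that("consistency ratio score matches hand arithmetic", {
  tab <- mini_table(list(c(1, 3), c(5, 7)))
  expect_equal(dice_score(tab, "F1"), 2.0, tolerance = 1e-12)
  # identical per-setting means: numerator vanishes
  tab0 <- mini_table(list(c(1, 3), c(1, 3)))
  expect_equal(dice_score(tab0, "F1"), 0)
})

test_that("per-setting t score matches hand arithmetic", {
  tab <- mini_table(list(c(1, 2, 3, 4, 5, 6)),
                    classes = rep(c("pos", "neg"), each = 3))
  expect_equal(ttest_score_setting(tab, "F1", 1), 3 / sqrt(2 / 3),
               tolerance = 1e-12)
  expect_equal(ttest_score_setting(tab, "F1", 1,
                                   form = "squared_numerator"),
               9 / sqrt(2 / 3), tolerance = 1e-12)
  # equal class means: zero numerator
  tabe <- mini_table(list(c(1, 2, 3, 1, 2, 3)),
                     classes = rep(c("pos", "neg"), each = 3))
  expect_equal(ttest_score_setting(tabe, "F1", 1), 0)
})

test_that("multi-setting t score normalizes by the score dispersion", {
  # setting 1 gives t = 3k, setting 2 gives t = k, so the combined
  # score is 4k / (2 * sqrt(2) k) = sqrt(2), as in the {3, 1} example
  tab <- mini_table(list(c(1, 2, 3, 4, 5, 6), c(1, 2, 3, 2, 3, 4)),
                    classes = rep(c("pos", "neg"), each = 3))
  expect_equal(as.numeric(ttest_score(tab, "F1")), sqrt(2),
               tolerance = 1e-12)
  expect_false(attr(ttest_score(tab, "F1"), "degenerate"))
  # identical per-setting scores: guarded, flagged
  tabd <- mini_table(list(c(1, 2, 3, 4, 5, 6), c(1, 2, 3, 4, 5, 6)),
                     classes = rep(c("pos", "neg"), each = 3))
  r <- ttest_score(tabd, "F1")
  expect_true(attr(r, "degenerate"))
  expect_gt(as.numeric(r), 1e10)
})

test_that("paired correlation matches hand values and edge cases", {
  tab <- mini_table(list(c(1, 2, 3), c(1, 3, 4)))
  expect_equal(pearson_pairwise(tab, "F1", 1, 2),
               cor(c(1, 2, 3), c(1, 3, 4)), tolerance = 1e-15)
  expect_equal(pearson_pairwise(tab, "F1", 1, 2), 0.9819805,
               tolerance = 1e-6)
  expect_equal(pearson_pairwise(mini_table(list(1:4, 1:4)), "F1", 1, 2), 1)
  expect_equal(pearson_pairwise(mini_table(list(1:4, -(1:4))), "F1", 1, 2),
               -1)
  # zero variance reported as 0
  expect_equal(pearson_pairwise(mini_table(list(rep(2, 4), 1:4)),
                                "F1", 1, 2), 0)
})

test_that("per-setting and overall correlation scores follow Eq structure", {
  # three settings: x2 = x1 (r = 1), x3 = -x1 (r = -1)
  tab <- mini_table(list(c(1, 2, 4), c(1, 2, 4), c(-1, -2, -4)))
  expect_equal(pearson_setting(tab, "F1", 1), 1)
  r <- pearson_score(tab, "F1")
  expect_true(attr(r, "degenerate"))  # all Cor_i equal 1
  # non-degenerate: verify against a literal second-path computation
  set.seed(7)
  tab2 <- mini_table(list(rnorm(10), rnorm(10), rnorm(10)))
  cor_i <- vapply(1:3, function(i) {
    mean(vapply(setdiff(1:3, i), function(j) {
      a <- tab2$F1[tab2$setting_id == i]
      b <- tab2$F1[tab2$setting_id == j]
      abs(cor(a, b))
    }, numeric(1)))
  }, numeric(1))
  expect_equal(as.numeric(pearson_score(tab2, "F1")),
               sum(cor_i) / (3 * sd(cor_i)), tolerance = 1e-12)
})

test_that("filter scores are invariant to affine feature rescaling", {
  tab <- planted_table(seed = 3, n = 20, n_features = 3)
  tab2 <- tab
  tab2$F1 <- 5 * tab$F1 - 7
  for (fn in list(dice_score,
                  function(t, f) as.numeric(ttest_score(t, f)),
                  function(t, f) as.numeric(pearson_score(t, f)))) {
    expect_equal(fn(tab, "F1"), fn(tab2, "F1"), tolerance = 1e-9)
  }
})

test_that("planted universal features outrank noise in the class-aware metrics", {
  tab <- planted_table(seed = 11, n = 100, n_features = 15, universal = 1:3)
  scores <- compute_filter_scores(tab)
  # t scores see the class separation; Pearson sees the extra pair-level
  # reproducibility the shared class effect induces across settings
  expect_true(all(scores$rank_ttest[1:3] <= 3))
  expect_true(all(scores$rank_pearson[1:3] <= 6))
  # the aggregate rank also averages in the class-blind setting-shift
  # ratio, so planted features need only land in its upper tier
  agg_order <- scores$feature[order(scores$rank_aggregate)]
  expect_true(all(match(paste0("F", 1:3), agg_order) <= 6))
})

test_that("setting-shift ratio score detects planted between-setting shifts", {
  # F1 drifts between settings, F2 does not; only F1 scores high
  set.seed(13)
  vals1 <- lapply(c(0, 3, 6), function(m) m + rnorm(40))
  vals2 <- lapply(c(0, 0, 0), function(m) m + rnorm(40))
  tab <- mini_table(vals1)
  tab$F2 <- unlist(vals2)
  expect_gt(dice_score(tab, "F1"), 10 * dice_score(tab, "F2"))
})

test_that("candidate pool keeps planted features and flags fallback", {
  tab <- planted_table(seed = 5, n = 60, n_features = 12, universal = 1:3)
  scores <- compute_filter_scores(tab)
  pool <- build_candidate_pool(scores, tab, top_n = 6,
                               config = svm_config(fold_seed = 2))
  expect_s3_class(pool, "candidate_pool")
  expect_true(all(c("F1", "F2", "F3") %in% pool$pool))
  expect_true(length(pool$pool) <= 6)
  # forced fallback: floor larger than any possible intersection
  pool2 <- build_candidate_pool(scores, tab, top_n = 6,
                                config = svm_config(fold_seed = 2),
                                floor = 12)
  expect_true(pool2$fallback_used)
  expect_error(
    build_candidate_pool(scores, tab, top_n = 13,
                         config = svm_config(fold_seed = 2)),
    "top_n"
  )
})
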