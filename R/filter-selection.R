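# A labeled feature table is a data.frame with columns sample_id,
# setting_id, pair_id, class (two-level factor) and feature columns
# F1..Fk.  These helpers validate and slice it.

feature_columns <- function(table) {
  grep("^F[0-9]+$", names(table), value = TRUE)
}

check_feature_table <- function(table) {
  needed <- c("sample_id", "setting_id", "pair_id", "class")
  missing <- setdiff(needed, names(table))
  if (length(missing)) {
    stop_invalid("feature table lacks column(s): ",
                 paste(missing, collapse = ", "))
  }
  if (length(unique(table$class)) != 2L) {
    stop_invalid("feature table must contain exactly two classes")
  }
  cnt <- table(table$setting_id, table$class)
  if (any(cnt < 2)) {
    stop_invalid("every setting needs at least 2 samples per class")
  }
  if (anyDuplicated(table[, c("setting_id", "pair_id")])) {
    stop_invalid("each pair_id may occur at most once per setting")
  }
  invisible(table)
}

#' Augmented Sorensen-Dice consistency score of one feature
#'
#' The ratio of the between-setting squared deviation of per-setting
#' feature means about the pooled mean to the sum of per-setting sample
#' variances.  Large values flag features whose typical level shifts
#' strongly between acquisition settings relative to their within-setting
#' spread.
#'
#' @param table Labeled feature table (see [generate_feature_table()]).
#' @param feature Feature column name (e.g. `"F4"`).
#' @param epsilon Guard replacing a vanishing denominator.
#' @return A single non-negative numeric score.
#' @export
dice_score <- function(table, feature, epsilon = 1e-12) {
  x <- table[[feature]]
  s <- table$setting_id
  setting_means <- tapply(x, s, mean)
  num <- sum((setting_means - mean(x))^2)
  den <- sum(tapply(x, s, stats::var))
  num / max(den, epsilon)
}

#' Per-setting two-sample t score of one feature
#'
#' The absolute Welch statistic `|m+ - m-| / sqrt(v+/n+ + v-/n-)` between
#' the two classes within one setting, using sample variances.  The
#' `squared_numerator` form squares the mean difference instead, matching
#' a literal reading of the originating formula; the standard form is the
#' default.
#'
#' @inheritParams dice_score
#' @param setting Setting identifier to restrict to.
#' @param form `"standard"` (absolute mean difference) or
#'   `"squared_numerator"`.
#' @return A single non-negative numeric score.
#' @export
ttest_score_setting <- function(table, feature, setting,
                                form = c("standard", "squared_numerator"),
                                epsilon = 1e-12) {
  form <- match.arg(form)
  rows <- table$setting_id == setting
  x <- table[[feature]][rows]
  cl <- factor(table$class[rows])
  lv <- levels(cl)
  if (length(lv) != 2L || any(table(cl) < 2)) {
    stop_invalid("setting ", setting,
                 " needs both classes with >= 2 samples each")
  }
  xp <- x[cl == lv[1]]
  xn <- x[cl == lv[2]]
  se <- sqrt(stats::var(xp) / length(xp) + stats::var(xn) / length(xn))
  num <- if (form == "standard") abs(mean(xp) - mean(xn)) else
    (mean(xp) - mean(xn))^2
  num / max(se, epsilon)
}

#' Multi-setting t score of one feature
#'
#' Per-setting t scores are summed and normalized by `s` times their
#' sample standard deviation across the `s` settings, so features that
#' discriminate the classes strongly *and* consistently across settings
#' score highest.  A vanishing dispersion (identical per-setting scores)
#' is replaced by `epsilon`; callers can detect this via the
#' `"degenerate"` attribute.
#'
#' @inheritParams ttest_score_setting
#' @return Numeric score with logical attribute `degenerate`.
#' @export
ttest_score <- function(table, feature,
                        form = c("standard", "squared_numerator"),
                        epsilon = 1e-12) {
  form <- match.arg(form)
  settings <- sort(unique(table$setting_id))
  tij <- vapply(settings, function(s) {
    ttest_score_setting(table, feature, s, form, epsilon)
  }, numeric(1))
  s <- length(settings)
  disp <- stats::sd(tij)
  structure(sum(tij) / (s * max(disp, epsilon)),
            degenerate = disp < epsilon)
}

#' Paired Pearson correlation of one feature between two settings
#'
#' Correlates the feature values of physically matched blocks (linked by
#' `pair_id`) between two settings.  Pairs missing from either setting
#' are dropped from this computation only.  If either vector has zero
#' variance the correlation is reported as 0.
#'
#' @inheritParams dice_score
#' @param setting_i,setting_j The two settings to compare.
#' @return Numeric in `[-1, 1]`.
#' @export
pearson_pairwise <- function(table, feature, setting_i, setting_j) {
  a <- table[table$setting_id == setting_i, c("pair_id", feature)]
  b <- table[table$setting_id == setting_j, c("pair_id", feature)]
  common <- intersect(a$pair_id, b$pair_id)
  if (length(common) < 2L) {
    stop_invalid("settings ", setting_i, " and ", setting_j,
                 " share fewer than 2 pair_ids")
  }
  xi <- a[[feature]][match(common, a$pair_id)]
  xj <- b[[feature]][match(common, b$pair_id)]
  if (stats::sd(xi) == 0 || stats::sd(xj) == 0) return(0)
  stats::cor(xi, xj)
}

#' Mean absolute paired correlation of one feature for one setting
#'
#' Average of `|r|` between the given setting and every other setting.
#'
#' @inheritParams pearson_pairwise
#' @return Numeric in `[0, 1]`.
#' @export
pearson_setting <- function(table, feature, setting_i) {
  others <- setdiff(sort(unique(table$setting_id)), setting_i)
  mean(vapply(others, function(sj) {
    abs(pearson_pairwise(table, feature, setting_i, sj))
  }, numeric(1)))
}

#' Multi-setting Pearson consistency score of one feature
#'
#' Per-setting mean absolute correlations are summed and normalized by
#' `s` times their sample standard deviation, rewarding features whose
#' paired reproducibility is both high and uniform across settings.  A
#' vanishing dispersion is epsilon-guarded and flagged via the
#' `"degenerate"` attribute.
#'
#' @inheritParams dice_score
#' @return Numeric score with logical attribute `degenerate`.
#' @export
pearson_score <- function(table, feature, epsilon = 1e-12) {
  settings <- sort(unique(table$setting_id))
  cor_i <- vapply(settings, function(s) {
    pearson_setting(table, feature, s)
  }, numeric(1))
  s <- length(settings)
  disp <- stats::sd(cor_i)
  structure(sum(cor_i) / (s * max(disp, epsilon)),
            degenerate = disp < epsilon)
}

#' Score every feature with the three filter metrics
#'
#' @inheritParams ttest_score_setting
#' @param features Feature columns to score; defaults to all `F*`
#'   columns.
#' @return A data.frame with one row per feature: the three scores, their
#'   degenerate-dispersion flags, per-metric ranks (1 = best, i.e.
#'   largest score) and the aggregate (mean) rank.
#' @export
compute_filter_scores <- function(table, features = NULL,
                                  form = c("standard", "squared_numerator"),
                                  epsilon = 1e-12) {
  check_feature_table(table)
  form <- match.arg(form)
  if (is.null(features)) features <- feature_columns(table)
  dice <- vapply(features, function(f) dice_score(table, f, epsilon),
                 numeric(1))
  tt <- lapply(features, function(f) ttest_score(table, f, form, epsilon))
  pr <- lapply(features, function(f) pearson_score(table, f, epsilon))
  scores <- data.frame(
    feature = features,
    dice = unname(dice),
    ttest = vapply(tt, as.numeric, numeric(1)),
    pearson = vapply(pr, as.numeric, numeric(1)),
    ttest_degenerate = vapply(tt, attr, logical(1), "degenerate"),
    pearson_degenerate = vapply(pr, attr, logical(1), "degenerate"),
    stringsAsFactors = FALSE
  )
  scores$rank_dice <- rank(-scores$dice, ties.method = "average")
  scores$rank_ttest <- rank(-scores$ttest, ties.method = "average")
  scores$rank_pearson <- rank(-scores$pearson, ties.method = "average")
  scores$rank_aggregate <-
    (scores$rank_dice + scores$rank_ttest + scores$rank_pearson) / 3
  scores
}

#' Single-feature classifier accuracy
#'
#' Five-fold cross-validated RBF-SVM accuracy using one feature alone,
#' computed per setting and averaged over settings.
#'
#' @inheritParams dice_score
#' @param config An [svm_config()].
#' @return Mean cross-validated accuracy in `[0, 1]`.
#' @export
single_feature_accuracy <- function(table, feature, config = svm_config()) {
  settings <- sort(unique(table$setting_id))
  acc <- vapply(settings, function(s) {
    rows <- table$setting_id == s
    x <- as.matrix(table[rows, feature, drop = FALSE])
    y <- factor(table$class[rows])
    svm_cross_validate(x, y, config)$mean_accuracy
  }, numeric(1))
  mean(acc)
}

#' Build the candidate feature pool for the wrapper stage
#'
#' Ranks features two ways - by aggregate filter-metric rank and by
#' single-feature cross-validated classifier accuracy - and intersects
#' the two top-`top_n` lists.  If the intersection is smaller than
#' `floor`, the union of the two lists, truncated to `top_n` by aggregate
#' rank, is used instead and the fallback is flagged.
#'
#' @param scores Output of [compute_filter_scores()].
#' @param table The labeled feature table the scores came from.
#' @param top_n Number of features kept on each list.
#' @param config An [svm_config()] for the accuracy ranking.
#' @param floor Minimum acceptable intersection size before the union
#'   fallback engages.
#' @param fallback Whether the union fallback is allowed; with
#'   `fallback = FALSE` an empty intersection is an error.
#' @return An object of class `candidate_pool`: a list with elements
#'   `pool` (selected feature names, ordered by aggregate rank),
#'   `list_metric`, `list_accuracy`, `accuracy` (named vector) and
#'   `fallback_used`.
#' @export
build_candidate_pool <- function(scores, table, top_n = 40L,
                                 config = svm_config(), floor = 5L,
                                 fallback = TRUE) {
  if (top_n > nrow(scores)) {
    stop_invalid("top_n (", top_n, ") exceeds the number of scored features")
  }
  by_metric <- scores$feature[order(scores$rank_aggregate,
                                    seq_len(nrow(scores)))]
  list_a <- by_metric[seq_len(top_n)]
  acc <- vapply(scores$feature, function(f) {
    single_feature_accuracy(table, f, config)
  }, numeric(1))
  list_b <- scores$feature[order(-acc, seq_len(nrow(scores)))][seq_len(top_n)]
  pool <- intersect(list_a, list_b)
  fallback_used <- FALSE
  if (length(pool) < floor) {
    if (!fallback) {
      if (length(pool) == 0L) {
        stop_invalid("candidate pool is empty and fallback is disabled")
      }
    } else {
      fallback_used <- TRUE
      pool <- union(list_a, list_b)
      pool <- by_metric[by_metric %in% pool]
      pool <- pool[seq_len(min(top_n, length(pool)))]
    }
  }
  pool <- by_metric[by_metric %in% pool]
  structure(
    list(pool = pool, list_metric = list_a, list_accuracy = list_b,
         accuracy = acc, fallback_used = fallback_used),
    class = "candidate_pool"
  )
}

#' @export
print.candidate_pool <- function(x, ...) {
  cat("Candidate feature pool (", length(x$pool), " features",
      if (x$fallback_used) ", union fallback" else "", ")\n", sep = "")
  cat(" ", paste(x$pool, collapse = ", "), "\n")
  invisible(x)
}
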