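#' Specification of a synthetic labeled feature table
#'
#' Describes a paired multi-setting two-class feature table with planted
#' structure.  Every physical block (identified by `pair_id`) is observed
#' once under each setting; "universal" informative features separate the
#' class means by `effect_size` within-class standard deviations in every
#' setting, while setting-specific informative features do so only in
#' their own setting.  All remaining features are pure noise.  Within a
#' class, each feature has unit total standard deviation, composed of a
#' shared latent pair effect (SD `pair_effect_sd`, which makes paired
#' observations of the same block correlate across settings) and
#' independent noise.  Each (feature, setting) combination also receives
#' a fixed mean shift with SD `cross_setting_noise`, emulating the
#' systematic level changes that different scanner settings induce.
#'
#' @param n_settings Number of acquisition settings.
#' @param n_per_class_per_setting Samples per class per setting.  The
#'   default (500, i.e. 4000 blocks over 4 settings with balanced
#'   classes) mirrors the scale of the motivating study's block
#'   collection; examples and tests pass smaller explicit sizes.
#' @param n_features Total number of feature columns `F1..Fk`.
#' @param universal_informative Integer feature indices informative in
#'   every setting.
#' @param setting_specific_informative List (length `n_settings`) of
#'   integer feature indices informative only in that setting.
#' @param effect_size Class-mean separation in within-class SD units.
#' @param cross_setting_noise SD of the per-(feature, setting) mean
#'   shift.
#' @param pair_effect_sd SD of the latent per-pair effect (must be < 1).
#' @param seed Integer seed.
#' @return Object of class `table_gen_spec`.
#' @export
table_gen_spec <- function(n_settings = 4L, n_per_class_per_setting = 500L,
                           n_features = 126L,
                           universal_informative = integer(0),
                           setting_specific_informative = list(),
                           effect_size = 2, cross_setting_noise = 0.25,
                           pair_effect_sd = 0.5, seed = 1L) {
  stopifnot(
    n_settings >= 2, n_per_class_per_setting >= 2, n_features >= 1,
    effect_size >= 0, cross_setting_noise >= 0,
    pair_effect_sd >= 0, pair_effect_sd < 1
  )
  specific <- unlist(setting_specific_informative, use.names = FALSE)
  all_inf <- c(universal_informative, specific)
  if (anyDuplicated(all_inf)) {
    stop_invalid("informative feature sets must be disjoint")
  }
  if (length(all_inf) && max(all_inf) > n_features) {
    stop_invalid("informative feature index exceeds n_features")
  }
  structure(list(
    n_settings = as.integer(n_settings),
    n_per_class_per_setting = as.integer(n_per_class_per_setting),
    n_features = as.integer(n_features),
    universal_informative = as.integer(universal_informative),
    setting_specific_informative =
      lapply(setting_specific_informative, as.integer),
    effect_size = effect_size,
    cross_setting_noise = cross_setting_noise,
    pair_effect_sd = pair_effect_sd,
    seed = as.integer(seed)
  ), class = "table_gen_spec")
}

#' Generate a synthetic labeled feature table
#'
#' @param spec A [table_gen_spec()].
#' @return A data.frame with columns `sample_id`, `setting_id`,
#'   `pair_id`, `class` (factor with levels `IDC`, `BM`) and feature
#'   columns `F1..Fk`; one row per pair per setting, balanced classes,
#'   deterministic for a fixed seed.
#' @export
generate_feature_table <- function(spec) {
  stopifnot(inherits(spec, "table_gen_spec"))
  s <- spec$n_settings
  npc <- spec$n_per_class_per_setting
  nf <- spec$n_features
  n_pairs <- 2L * npc
  pair_class <- factor(rep(c("IDC", "BM"), each = npc),
                       levels = c("IDC", "BM"))
  noise_sd <- sqrt(1 - spec$pair_effect_sd^2)

  with_seed(spec$seed, {
    setting_shift <- matrix(stats::rnorm(s * nf, 0, spec$cross_setting_noise),
                            s, nf)
    pair_effect <- matrix(stats::rnorm(n_pairs * nf, 0, spec$pair_effect_sd),
                          n_pairs, nf)
    rows <- vector("list", s)
    for (st in seq_len(s)) {
      informative <- c(spec$universal_informative,
                       if (st <= length(spec$setting_specific_informative))
                         spec$setting_specific_informative[[st]])
      x <- matrix(stats::rnorm(n_pairs * nf, 0, noise_sd), n_pairs, nf)
      x <- x + pair_effect
      x <- sweep(x, 2, setting_shift[st, ], "+")
      if (length(informative)) {
        x[pair_class == "IDC", informative] <-
          x[pair_class == "IDC", informative] + spec$effect_size
      }
      colnames(x) <- paste0("F", seq_len(nf))
      rows[[st]] <- data.frame(
        sample_id = sprintf("S%d_P%d", st, seq_len(n_pairs)),
        setting_id = st,
        pair_id = seq_len(n_pairs),
        class = pair_class,
        x,
        stringsAsFactors = FALSE
      )
    }
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
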