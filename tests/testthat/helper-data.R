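# Shared fixture builders (all generated in code, seeded).

random_block <- function(seed, nr = 23, nc = nr, max_val = 255) {
  set.seed(seed)
  matrix(sample(0:max_val, nr * nc, replace = TRUE), nr, nc)
}

# Minimal labeled table from explicit per-setting feature values.
mini_table <- function(values_by_setting, classes = NULL) {
  rows <- lapply(seq_along(values_by_setting), function(s) {
    v <- values_by_setting[[s]]
    data.frame(
      sample_id = sprintf("S%d_P%d", s, seq_along(v)),
      setting_id = s,
      pair_id = seq_along(v),
      class = if (is.null(classes)) rep(c("A", "B"), length.out = length(v))
              else classes,
      F1 = v,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  out$class <- factor(out$class)
  out
}

# Standard planted-structure table used across GA/filter tests.
planted_table <- function(seed = 1, n = 100, n_features = 20,
                          universal = 1:3, effect = 2, settings = 4) {
  generate_feature_table(table_gen_spec(
    n_settings = settings, n_per_class_per_setting = n,
    n_features = n_features, universal_informative = universal,
    effect_size = effect, seed = seed
  ))
}
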