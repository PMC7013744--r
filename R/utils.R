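# Internal helpers shared across modules.

# sample() interprets a length-1 numeric vector as 1:n; resample() never does.
resample <- function(x, size, replace = FALSE, prob = NULL) {
  x[sample.int(length(x), size, replace = replace, prob = prob)]
}

# Run `code` under a fixed seed without disturbing the caller's RNG stream.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  force(code)
}

# Population (divide-by-n) variance and SD: the convention used for all
# image-domain statistics.  Tabular statistics use stats::var / stats::sd.
pop_var <- function(x) mean((x - mean(x))^2)
pop_sd <- function(x) sqrt(pop_var(x))

# Shannon entropy in bits of a probability vector; 0 * log 0 := 0.
entropy_bits <- function(p) {
  p <- p[p > 0]
  -sum(p * log2(p))
}

is_count <- function(x) is.numeric(x) && length(x) == 1L && !is.na(x) &&
  x == as.integer(x)

stop_invalid <- function(...) stop(..., call. = FALSE)
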