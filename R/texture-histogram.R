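#' First-order histogram features of a gray-level block
#'
#' Computes the seven first-order statistics of the pixel gray-level
#' distribution: energy and entropy of the normalized histogram, and the
#' ordinary moments (mean, variance, standard deviation, skewness,
#' kurtosis) of the pixel values.  Entropy is in bits; variance and
#' standard deviation use the population (divide-by-n) convention, and
#' skewness/kurtosis are the standardized third and fourth moments,
#' defined as 0 for a constant block (zero-variance convention).
#'
#' @param block Numeric matrix of gray values (raw, unquantized).
#' @return Named numeric vector of length 7, in feature-bank order:
#'   energy, entropy, kurtosis, mean, skewness, sd, variance.
#' @export
histogram_features <- function(block) {
  check_gray_block(block)
  v <- as.numeric(block)
  p <- as.numeric(table(v)) / length(v)
  mu <- mean(v)
  m2 <- mean((v - mu)^2)
  sdev <- sqrt(m2)
  if (sdev > 0) {
    skew <- mean((v - mu)^3) / sdev^3
    kurt <- mean((v - mu)^4) / sdev^4
  } else {
    skew <- 0
    kurt <- 0
  }
  c(
    energy = sum(p^2),
    entropy = entropy_bits(p),
    kurtosis = kurt,
    mean = mu,
    skewness = skew,
    sd = sdev,
    variance = m2
  )
}
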