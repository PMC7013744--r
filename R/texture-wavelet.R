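#' One-level Haar LL subband
#'
#' A single level of the separable orthonormal Haar discrete wavelet
#' transform, keeping only the low-pass/low-pass quadrant.  Odd dimensions
#' are handled by symmetric half-point extension (the final sample is
#' repeated), so an `n x m` block yields a `ceil(n/2) x ceil(m/2)`
#' subband; a 23x23 block yields 12x12.  With the orthonormal filter the
#' low-pass gain is `sqrt(2)` per dimension, so a constant block of value
#' `c` maps to a constant subband of value `2c`.
#'
#' @param block Numeric matrix, at least 2x2.
#' @return Numeric matrix holding the LL subband.
#' @export
wavelet_ll <- function(block) {
  check_gray_block(block, min_dim = 2L)
  low <- function(m) {
    if (nrow(m) %% 2 == 1) m <- rbind(m, m[nrow(m), , drop = FALSE])
    odd <- seq(1, nrow(m), by = 2)
    (m[odd, , drop = FALSE] + m[odd + 1, , drop = FALSE]) / sqrt(2)
  }
  t(low(t(low(block))))
}
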