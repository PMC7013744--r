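# Neighbor offsets (row, col) in fixed clockwise order starting east.
fourier_neighbor_offsets <- function() {
  matrix(c(
     0L,  1L,   # E
     1L,  1L,   # SE
     1L,  0L,   # S
     1L, -1L,   # SW
     0L, -1L,   # W
    -1L, -1L,   # NW
    -1L,  0L,   # N
    -1L,  1L    # NE
  ), ncol = 2, byrow = TRUE)
}

#' Local Fourier coefficient features
#'
#' For every interior pixel, the eight neighbors are read in clockwise
#' order starting east and transformed by the unnormalized 8-point
#' discrete Fourier transform.  The 32 features are the means of the eight
#' coefficient magnitudes, the means of the eight phase angles, the
#' (population) standard deviations of the magnitudes and the standard
#' deviations of the phase angles, each taken over all interior pixels.
#' Phases use the two-argument arctangent in (-pi, pi]; real or
#' imaginary components below 1e-8 in magnitude are treated as exact
#' zeros, and a zero coefficient has phase 0.
#'
#' @param block Numeric matrix, at least 3x3.
#' @return Named numeric vector of length 32.
#' @export
local_fourier_features <- function(block) {
  check_gray_block(block, min_dim = 3L)
  nr <- nrow(block); nc <- ncol(block)
  ri <- 2:(nr - 1)
  ci <- 2:(nc - 1)
  off <- fourier_neighbor_offsets()
  nb <- vapply(seq_len(8), function(k) {
    as.vector(block[ri + off[k, 1], ci + off[k, 2], drop = FALSE])
  }, numeric(length(ri) * length(ci)))
  if (!is.matrix(nb)) nb <- matrix(nb, nrow = 1)
  w <- exp(-2i * pi * outer(0:7, 0:7) / 8)
  coef <- nb %*% w                       # interior pixels x 8 frequencies
  # components below 1e-8 are rounding residue of exact zeros; snapping
  # them keeps the phase angle well defined at the +/- pi boundary
  re <- Re(coef); im <- Im(coef)
  re[abs(re) < 1e-8] <- 0
  im[abs(im) < 1e-8] <- 0
  mag <- sqrt(re^2 + im^2)
  ph <- atan2(im, re)
  ph[mag == 0] <- 0
  u <- 0:7
  stats::setNames(
    c(colMeans(mag), colMeans(ph),
      apply(mag, 2, pop_sd), apply(ph, 2, pop_sd)),
    c(paste0("magnitude_mean_u", u), paste0("phase_mean_u", u),
      paste0("magnitude_sd_u", u), paste0("phase_sd_u", u))
  )
}
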