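#' Gray-level co-occurrence (spatial dependence) matrix
#'
#' Counts ordered pairs of quantized gray levels separated by the given
#' displacement, symmetrizes (both directions of the displacement count),
#' and normalizes to sum to 1.
#'
#' @param q Integer matrix of quantized gray levels in `0 .. levels - 1`.
#' @param levels Number of gray levels.
#' @param angle Displacement angle in degrees (0, 45, 90 or 135).
#' @param d Displacement length in pixels.
#' @return A `levels` x `levels` matrix summing to 1.
#' @export
glcm_matrix <- function(q, levels, angle, d = 1L) {
  off <- angle_offset(angle, d)
  dr <- off[1]; dc <- off[2]
  nr <- nrow(q); nc <- ncol(q)
  rows <- max(1, 1 - dr):min(nr, nr - dr)
  cols <- max(1, 1 - dc):min(nc, nc - dc)
  if (min(nr, nr - abs(dr)) < 1 || min(nc, nc - abs(dc)) < 1 ||
      length(rows) < 1 || length(cols) < 1 ||
      nr - abs(dr) < 1 || nc - abs(dc) < 1) {
    stop_invalid("displacement (", dr, ",", dc, ") exceeds image size")
  }
  a <- q[rows, cols, drop = FALSE]
  b <- q[rows + dr, cols + dc, drop = FALSE]
  counts <- tabulate(as.vector(a) * levels + as.vector(b) + 1L,
                     nbins = levels * levels)
  cmat <- matrix(counts, levels, levels, byrow = TRUE)
  cmat <- cmat + t(cmat)
  cmat / sum(cmat)
}

# The 13 co-occurrence descriptors from one normalized symmetric matrix.
glcm_features_one <- function(P, levels) {
  g <- 0:(levels - 1)
  i <- matrix(g, levels, levels)
  j <- t(i)
  px <- rowSums(P)
  mux <- sum(g * px)
  sdx <- sqrt(sum((g - mux)^2 * px))
  # P is symmetric, so x and y marginals coincide.
  sums <- as.vector(i + j)
  diffs <- as.vector(abs(i - j))
  p_sum <- as.vector(rowsum(as.vector(P), sums))     # k = 0 .. 2L-2
  k_sum <- sort(unique(sums))
  p_dif <- as.vector(rowsum(as.vector(P), diffs))    # k = 0 .. L-1
  k_dif <- sort(unique(diffs))

  sum_avg <- sum(k_sum * p_sum)
  dif_avg <- sum(k_dif * p_dif)
  corr <- if (sdx > 1e-12) (sum(i * j * P) - mux^2) / sdx^2 else 0

  c(
    correlation = corr,
    difference_entropy = entropy_bits(p_dif),
    difference_variance = sum((k_dif - dif_avg)^2 * p_dif),
    sum_average = sum_avg,
    sum_entropy = entropy_bits(p_sum),
    sum_of_squares = sum((i - mux)^2 * P),
    sum_variance = sum((k_sum - sum_avg)^2 * p_sum),
    contrast = sum((i - j)^2 * P),
    energy = sum(P^2),
    entropy = entropy_bits(as.vector(P)),
    local_homogeneity = sum(P / (1 + (i - j)^2)),
    cluster_shade = sum((i + j - 2 * mux)^3 * P),
    cluster_prominence = sum((i + j - 2 * mux)^4 * P)
  )
}

#' Co-occurrence texture features
#'
#' The 13 Haralick-style descriptors of the gray-level spatial dependence
#' matrix, computed per angle and averaged over the configured angle set.
#'
#' @inheritParams glcm_matrix
#' @param angles Vector of angles in degrees to average over.
#' @return Named numeric vector of length 13 in feature-bank order
#'   (correlation, difference entropy, difference variance, sum average,
#'   sum entropy, sum of squares, sum variance, contrast, energy, entropy,
#'   local homogeneity, cluster shade, cluster prominence).
#' @export
glcm_features <- function(q, levels, angles = c(0, 45, 90, 135), d = 1L) {
  per_angle <- vapply(
    angles,
    function(a) glcm_features_one(glcm_matrix(q, levels, a, d), levels),
    numeric(13)
  )
  rowMeans(per_angle)
}
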