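# Dependence count k for every interior pixel: the number of neighbors
# within Chebyshev distance d whose quantized level differs by at most a.
ngldm_dependence <- function(q, d = 1L, a = 0L) {
  nr <- nrow(q); nc <- ncol(q)
  if (nr < 2 * d + 1 || nc < 2 * d + 1) {
    stop_invalid("block too small for neighborhood distance ", d)
  }
  ri <- (1 + d):(nr - d)
  ci <- (1 + d):(nc - d)
  centers <- q[ri, ci, drop = FALSE]
  k <- matrix(0L, length(ri), length(ci))
  for (dr in -d:d) {
    for (dc in -d:d) {
      if (dr == 0 && dc == 0) next
      k <- k + (abs(q[ri + dr, ci + dc, drop = FALSE] - centers) <= a)
    }
  }
  list(levels = centers, k = k)
}

#' Neighboring gray-level dependence features
#'
#' Builds the dependence matrix `Q(g, k)` counting interior pixels of
#' quantized level `g` that have exactly `k` neighbors (within Chebyshev
#' distance `d`) whose level differs by at most the tolerance `a`, and
#' returns small number emphasis, large number emphasis, number
#' non-uniformity, second moment and entropy (all normalized by the total
#' count; entropy in bits).  Cells with dependence `k = 0` contribute
#' nothing to small number emphasis but do count in the normalization.
#'
#' @param q Integer matrix of quantized gray levels.
#' @param d Neighborhood Chebyshev distance in pixels.
#' @param a Gray-level tolerance.
#' @return Named numeric vector of length 5.
#' @export
ngldm_features <- function(q, d = 1L, a = 0L) {
  dep <- ngldm_dependence(q, d, a)
  # Q as a cross-tabulation over (level, dependence count).
  tab <- table(level = as.vector(dep$levels), k = as.vector(dep$k))
  qcounts <- as.numeric(tab)
  kvals <- as.numeric(colnames(tab))[as.vector(col(tab))]
  n <- sum(qcounts)
  p <- qcounts / n
  sne_terms <- ifelse(kvals >= 1, qcounts / pmax(kvals, 1)^2, 0)
  per_k <- rowsum(qcounts, kvals)
  c(
    small_number_emphasis = sum(sne_terms) / n,
    large_number_emphasis = sum(qcounts * kvals^2) / n,
    number_non_uniformity = sum(per_k^2) / n,
    second_moment = sum(qcounts^2) / n,
    entropy = entropy_bits(p)
  )
}

#' Neighborhood gray-tone difference features
#'
#' For each interior pixel the absolute difference between its quantized
#' level and the mean of its `(2d+1)^2 - 1` neighbors is accumulated per
#' gray level into `s(g)`; the five classic descriptors (busyness,
#' coarseness, complexity, contrast, textural strength) are computed from
#' `s(g)` and the interior level probabilities, with `epsilon` guarding
#' denominators that vanish on flat blocks.
#'
#' @inheritParams ngldm_features
#' @param epsilon Small positive guard for zero denominators.
#' @return Named numeric vector of length 5, in feature-bank order
#'   (busyness, coarseness, complexity, contrast, strength).
#' @export
ngtdm_features <- function(q, d = 1L, epsilon = 1e-6) {
  nr <- nrow(q); nc <- ncol(q)
  if (nr < 2 * d + 1 || nc < 2 * d + 1) {
    stop_invalid("block too small for neighborhood distance ", d)
  }
  ri <- (1 + d):(nr - d)
  ci <- (1 + d):(nc - d)
  centers <- q[ri, ci, drop = FALSE]
  acc <- matrix(0, length(ri), length(ci))
  n_nb <- (2 * d + 1)^2 - 1
  for (dr in -d:d) {
    for (dc in -d:d) {
      if (dr == 0 && dc == 0) next
      acc <- acc + q[ri + dr, ci + dc, drop = FALSE]
    }
  }
  diffs <- abs(as.vector(centers) - as.vector(acc) / n_nb)
  lv <- as.vector(centers)
  gi <- sort(unique(lv))
  s <- as.vector(rowsum(diffs, lv))        # s(g) for present levels
  n_g <- as.vector(rowsum(rep(1, length(lv)), lv))
  n <- length(lv)
  p <- n_g / n
  ng <- length(gi)

  busy_den <- sum(abs(outer(gi * p, gi * p, "-")))
  contrast <- if (ng > 1) {
    (sum(outer(p, p) * outer(gi, gi, "-")^2) / (ng * (ng - 1))) * (sum(s) / n)
  } else 0
  pij <- outer(p, p, "+")
  complexity <- sum(abs(outer(gi, gi, "-")) * outer(p * s, p * s, "+") /
                      (n * pij))
  strength <- sum(pij * outer(gi, gi, "-")^2) / (epsilon + sum(s))

  c(
    busyness = sum(p * s) / max(busy_den, epsilon),
    coarseness = 1 / (epsilon + sum(p * s)),
    complexity = complexity,
    contrast = contrast,
    strength = strength
  )
}
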