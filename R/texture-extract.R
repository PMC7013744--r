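#' Configuration of the texture feature bank
#'
#' Bundles every tunable parameter of the matrix-family descriptors.
#' Defaults follow common texture-analysis practice: 32 gray levels for
#' all quantized families, unit displacement averaged over the four
#' standard angles for the co-occurrence, dissimilarity and run-length
#' families, an eight-neighborhood with zero tolerance for the dependence
#' and gray-tone difference families, the classic L5/E5/S5 Laws vectors,
#' a one-level orthonormal Haar transform for the LL subband, and a small
#' epsilon guarding degenerate denominators.
#'
#' @param quant_levels Gray levels used by all matrix families (2..256).
#' @param glcm_distance,glcm_angles Co-occurrence displacement length and
#'   angle set (degrees).
#' @param glrlm_directions Run-length direction set (degrees).
#' @param sfm_angles Displacement angles for the dissimilarity feature.
#' @param ngldm_distance,ngldm_tolerance Dependence-matrix neighborhood
#'   distance and gray-level tolerance.
#' @param ngtdm_distance Gray-tone-difference neighborhood distance.
#' @param laws Named list of the three length-5 Laws vectors (`L`, `E`,
#'   `S`).
#' @param epsilon Guard for zero denominators.
#' @return An object of class `texture_config`.
#' @export
texture_config <- function(quant_levels = 32L,
                           glcm_distance = 1L,
                           glcm_angles = c(0, 45, 90, 135),
                           glrlm_directions = c(0, 45, 90, 135),
                           sfm_angles = c(0, 45, 90, 135),
                           ngldm_distance = 1L,
                           ngldm_tolerance = 0L,
                           ngtdm_distance = 1L,
                           laws = laws_vectors(),
                           epsilon = 1e-6) {
  stopifnot(
    quant_levels >= 2, quant_levels <= 256,
    glcm_distance >= 1, ngldm_distance >= 1, ngtdm_distance >= 1,
    epsilon > 0,
    all(lengths(laws[c("L", "E", "S")]) == 5)
  )
  structure(
    list(
      quant_levels = as.integer(quant_levels),
      glcm_distance = as.integer(glcm_distance),
      glcm_angles = glcm_angles,
      glrlm_directions = glrlm_directions,
      sfm_angles = sfm_angles,
      ngldm_distance = as.integer(ngldm_distance),
      ngldm_tolerance = as.integer(ngldm_tolerance),
      ngtdm_distance = as.integer(ngtdm_distance),
      laws = laws,
      epsilon = epsilon
    ),
    class = "texture_config"
  )
}

#' Wavelet-domain texture features
#'
#' Recomputes the histogram, co-occurrence, dissimilarity, run-length,
#' Laws, dependence and gray-tone difference families on the one-level
#' Haar LL subband, after re-quantizing the subband to
#' `cfg$quant_levels`.  Two extra raw-subband statistics - the LL mean and
#' (population) standard deviation - are inserted between the run-length
#' and Laws groups, matching the feature-bank numbering.
#'
#' @param block Numeric matrix, at least 9x9 (so the subband admits the
#'   5x5 Laws masks).
#' @param cfg A [texture_config()].
#' @return Named numeric vector of length 48.
#' @export
wavelet_features <- function(block, cfg = texture_config()) {
  ll <- wavelet_ll(block)
  q <- quantize_gray(ll, cfg$quant_levels)
  out <- c(
    histogram_features(q),
    glcm_features(q, cfg$quant_levels, cfg$glcm_angles, cfg$glcm_distance),
    dissimilarity = sfm_dissimilarity(q, cfg$sfm_angles, cfg$glcm_distance),
    glrlm_features(q, cfg$quant_levels, cfg$glrlm_directions),
    ll_mean = mean(ll),
    ll_sd = pop_sd(as.numeric(ll)),
    laws_features(q, cfg$laws),
    ngldm_features(q, cfg$ngldm_distance, cfg$ngldm_tolerance),
    ngtdm_features(q, cfg$ngtdm_distance, cfg$epsilon)
  )
  stats::setNames(out, paste0("wavelet_", names(out)))
}

#' Extract the full 126-feature texture vector from one block
#'
#' Concatenates, in fixed feature-bank order F1..F126: the 7 histogram
#' features, 13 co-occurrence features, the dissimilarity feature, 5
#' run-length features, 10 Laws features, 5 dependence features, 5
#' gray-tone difference features (all computed on the raw or quantized
#' block as appropriate), the 48 wavelet-domain features and the 32 local
#' Fourier features.  Histogram, Laws and Fourier features are computed
#' on the raw gray values; the matrix families use the block quantized to
#' `cfg$quant_levels`.
#'
#' @param block Numeric matrix of gray values, at least 9x9 (23x23 in the
#'   standard tiling).
#' @param cfg A [texture_config()].
#' @return Named numeric vector of length 126 with names `F1` .. `F126`;
#'   the descriptive names are available via [feature_names()].
#' @examples
#' blk <- matrix(sample(0:255, 23 * 23, replace = TRUE), 23, 23)
#' fv <- extract_features(blk)
#' length(fv)
#' @export
extract_features <- function(block, cfg = texture_config()) {
  check_gray_block(block, min_dim = 9L)
  q <- quantize_gray(block, cfg$quant_levels)
  out <- c(
    histogram_features(block),
    glcm_features(q, cfg$quant_levels, cfg$glcm_angles, cfg$glcm_distance),
    dissimilarity = sfm_dissimilarity(q, cfg$sfm_angles, cfg$glcm_distance),
    glrlm_features(q, cfg$quant_levels, cfg$glrlm_directions),
    laws_features(block, cfg$laws),
    ngldm_features(q, cfg$ngldm_distance, cfg$ngldm_tolerance),
    ngtdm_features(q, cfg$ngtdm_distance, cfg$epsilon),
    wavelet_features(block, cfg),
    local_fourier_features(block)
  )
  stopifnot(length(out) == 126L)
  if (any(!is.finite(out))) {
    stop_invalid("non-finite feature value produced: ",
                 paste(names(out)[!is.finite(out)], collapse = ", "))
  }
  stats::setNames(out, paste0("F", seq_len(126)))
}

#' Descriptive names of the 126 texture features
#'
#' @return Character vector of length 126; element `i` names feature
#'   `Fi`.
#' @examples
#' feature_names()[4] # "Mean"
#' @export
feature_names <- function() {
  hist_names <- c("Energy", "Entropy", "Kurtosis", "Mean", "Skewness",
                  "Standard Deviation", "Variance")
  glcm_names <- c("Correlation", "Difference of entropy",
                  "Difference of variance", "Sum of average",
                  "Sum of entropy", "Sum of squares", "Sum of variance",
                  "Contrast", "Energy (GLSDM)", "Entropy (GLSDM)",
                  "Local homogeneity", "Cluster shade",
                  "Cluster prominence")
  glrlm_names <- c("Short-run emphasis", "Long-run emphasis",
                   "Gray-level uniformity", "Run-length uniformity",
                   "Run percentage")
  laws_names <- c(paste(c("LE", "EL", "SL", "EE", "LS"), "mean"),
                  paste(c("LE", "EL", "SL", "EE", "LS"), "variance"))
  ngldm_names <- c("Small number emphasis", "Large number emphasis",
                   "Number non-uniformity", "Second moment",
                   "Entropy (NGLDM)")
  ngtdm_names <- c("Busyness", "Coarseness", "Complexity",
                   "Contrast (NGTDM)", "Textural Strength")
  u <- 0:7
  c(
    hist_names,
    glcm_names,
    "Dissimilarity",
    glrlm_names,
    laws_names,
    ngldm_names,
    ngtdm_names,
    paste("Wavelet", c(hist_names, glcm_names, "Dissimilarity",
                       glrlm_names, "Mean", "Standard deviation",
                       laws_names, ngldm_names, ngtdm_names)),
    paste0("Mean of magnitude u", u),
    paste0("Mean of phase angle u", u),
    paste0("SD of magnitude u", u),
    paste0("SD of phase angle u", u)
  )
}
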