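#' Quantize a grayscale image to a fixed number of gray levels
#'
#' Maps pixel values onto the integer levels `0 .. levels - 1` by monotone
#' linear min-max binning: the observed intensity range is split into
#' `levels` equal-width bins.  A constant image has no range and maps
#' entirely to level 0.  All matrix-family texture descriptors
#' (co-occurrence, run-length, dependence, gray-tone difference) operate on
#' the quantized image so that their matrices stay small and comparably
#' scaled across blocks.
#'
#' @param pixels Numeric or integer matrix of gray values.
#' @param levels Number of output gray levels, between 2 and 256.
#' @return Integer matrix of the same shape with values in
#'   `0 .. levels - 1`.
#' @examples
#' quantize_gray(matrix(c(0, 100, 255), 1), levels = 2)
#' @export
quantize_gray <- function(pixels, levels) {
  check_gray_block(pixels)
  if (!is_count(levels) || levels < 2 || levels > 256) {
    stop_invalid("`levels` must be an integer in [2, 256]")
  }
  lo <- min(pixels)
  hi <- max(pixels)
  if (hi == lo) {
    q <- matrix(0L, nrow(pixels), ncol(pixels))
    return(q)
  }
  q <- floor((pixels - lo) / (hi - lo) * levels)
  q[q >= levels] <- levels - 1
  storage.mode(q) <- "integer"
  q
}

# Validate a grayscale block: non-empty numeric matrix, all finite.
check_gray_block <- function(pixels, min_dim = 1L) {
  if (!is.matrix(pixels) || !is.numeric(pixels) || length(pixels) == 0L) {
    stop_invalid("image block must be a non-empty numeric matrix")
  }
  if (any(!is.finite(pixels))) {
    stop_invalid("image block contains non-finite pixel values")
  }
  if (nrow(pixels) < min_dim || ncol(pixels) < min_dim) {
    stop_invalid("image block must be at least ", min_dim, "x", min_dim)
  }
  invisible(pixels)
}

# Row/column offset of a displacement of length d at one of the four
# standard texture angles (degrees).  0 deg points east, 45 north-east,
# 90 north, 135 north-west, in image coordinates (row increases downward).
angle_offset <- function(angle, d = 1L) {
  switch(as.character(angle),
    "0"   = c(0L, d),
    "45"  = c(-d, d),
    "90"  = c(-d, 0L),
    "135" = c(-d, -d),
    stop_invalid("unsupported angle: ", angle,
                 " (supported: 0, 45, 90, 135)")
  )
}
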