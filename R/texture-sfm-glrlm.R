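#' Statistical-feature-matrix dissimilarity
#'
#' Mean absolute gray-level difference between pixels separated by each
#' configured displacement, averaged over the displacement set.
#'
#' @inheritParams glcm_features
#' @return A single numeric value.
#' @export
sfm_dissimilarity <- function(q, angles = c(0, 45, 90, 135), d = 1L) {
  check_gray_block(q, min_dim = 2L)
  per_angle <- vapply(angles, function(a) {
    off <- angle_offset(a, d)
    dr <- off[1]; dc <- off[2]
    nr <- nrow(q); nc <- ncol(q)
    rows <- max(1, 1 - dr):min(nr, nr - dr)
    cols <- max(1, 1 - dc):min(nc, nc - dc)
    if (nr - abs(dr) < 1 || nc - abs(dc) < 1) {
      stop_invalid("displacement (", dr, ",", dc, ") exceeds image size")
    }
    a_ <- q[rows, cols, drop = FALSE]
    b_ <- q[rows + dr, cols + dc, drop = FALSE]
    mean(abs(a_ - b_))
  }, numeric(1))
  mean(per_angle)
}

# Decompose the matrix into its scan lines along one direction; within each
# line, pixels are ordered along the direction of travel.
direction_lines <- function(q, angle) {
  v <- as.vector(q)
  switch(as.character(angle),
    "0"   = split(v, as.vector(row(q))),
    "90"  = split(v, as.vector(col(q))),
    "45"  = split(v, as.vector(row(q) + col(q))),
    "135" = split(v, as.vector(col(q) - row(q))),
    stop_invalid("unsupported direction: ", angle)
  )
}

# Run-length matrix for one direction: counts[g + 1, l] = number of maximal
# runs of level g with length l.
glrlm_matrix <- function(q, levels, angle) {
  lines <- direction_lines(q, angle)
  max_len <- max(nrow(q), ncol(q))
  counts <- matrix(0, levels, max_len)
  for (ln in lines) {
    r <- rle(ln)
    for (k in seq_along(r$lengths)) {
      counts[r$values[k] + 1L, r$lengths[k]] <-
        counts[r$values[k] + 1L, r$lengths[k]] + 1
    }
  }
  counts
}

glrlm_features_one <- function(counts, n_pixels) {
  n_runs <- sum(counts)
  l <- seq_len(ncol(counts))
  runs_per_len <- colSums(counts)
  runs_per_lvl <- rowSums(counts)
  c(
    short_run_emphasis = sum(runs_per_len / l^2) / n_runs,
    long_run_emphasis = sum(runs_per_len * l^2) / n_runs,
    gray_level_uniformity = sum(runs_per_lvl^2) / n_runs,
    run_length_uniformity = sum(runs_per_len^2) / n_runs,
    run_percentage = n_runs / n_pixels
  )
}

#' Run-length texture features
#'
#' Maximal runs of constant quantized gray level are counted along each
#' configured direction; the five run-length descriptors (short-run
#' emphasis, long-run emphasis, gray-level uniformity, run-length
#' uniformity, run percentage) are computed per direction and averaged.
#'
#' @inheritParams glcm_features
#' @param directions Vector of directions in degrees to average over.
#' @return Named numeric vector of length 5.
#' @export
glrlm_features <- function(q, levels, directions = c(0, 45, 90, 135)) {
  check_gray_block(q)
  per_dir <- vapply(
    directions,
    function(a) glrlm_features_one(glrlm_matrix(q, levels, a), length(q)),
    numeric(5)
  )
  rowMeans(per_dir)
}
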