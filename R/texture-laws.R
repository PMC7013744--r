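# 2-D convolution, valid region only (kernel flipped, true convolution).
conv2_valid <- function(x, k) {
  kr <- nrow(k); kc <- ncol(k)
  nr <- nrow(x) - kr + 1L
  nc <- ncol(x) - kc + 1L
  if (nr < 1 || nc < 1) {
    stop_invalid("image (", nrow(x), "x", ncol(x),
                 ") smaller than kernel (", kr, "x", kc, ")")
  }
  out <- matrix(0, nr, nc)
  for (a in seq_len(kr)) {
    for (b in seq_len(kc)) {
      out <- out + k[a, b] *
        x[(kr - a + 1):(kr - a + nr), (kc - b + 1):(kc - b + nc)]
    }
  }
  out
}

#' Laws texture energy features
#'
#' Convolves the block with five 5x5 Laws masks and summarizes the
#' absolute responses.  Each mask is the outer product of two of the
#' classic length-5 vectors level `L5 = (1,4,6,4,1)`, edge
#' `E5 = (-1,-2,0,2,1)` and spot `S5 = (-1,0,2,0,-1)`; the first letter
#' names the row (vertical) factor and the second the column (horizontal)
#' factor.  Only the valid interior of the convolution is used.  The mean
#' of each absolute response map is returned first for all five masks (LE,
#' EL, SL, EE, LS), then the population variances in the same order.
#'
#' @param block Numeric matrix, at least 5x5.
#' @param vectors Named list with elements `L`, `E`, `S`: the three
#'   length-5 filter vectors.
#' @return Named numeric vector of length 10.
#' @export
laws_features <- function(block, vectors = laws_vectors()) {
  check_gray_block(block, min_dim = 5L)
  combos <- c("LE", "EL", "SL", "EE", "LS")
  resp <- lapply(combos, function(nm) {
    u <- vectors[[substr(nm, 1, 1)]]
    v <- vectors[[substr(nm, 2, 2)]]
    abs(conv2_valid(block, outer(u, v)))
  })
  means <- vapply(resp, mean, numeric(1))
  vars <- vapply(resp, pop_var, numeric(1))
  stats::setNames(
    c(means, vars),
    c(paste0(tolower(combos), "_mean"), paste0(tolower(combos), "_variance"))
  )
}

#' @rdname laws_features
#' @export
laws_vectors <- function() {
  list(
    L = c(1, 4, 6, 4, 1),
    E = c(-1, -2, 0, 2, 1),
    S = c(-1, 0, 2, 0, -1)
  )
}
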