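#' Specification of a synthetic paired texture image dataset
#'
#' Describes two-class textured grayscale blocks observed under several
#' emulated acquisition settings.  Each physical block is a stationary
#' Gaussian random field (white noise smoothed with a class-specific
#' kernel width, so the classes differ in texture scale), shared across
#' settings; each setting applies its own monotone intensity transform -
#' a gain followed by power-law dynamic-range compression - before 8-bit
#' quantization.  Because the transforms are monotone, paired blocks
#' retain the pixel ordering of their base field, mimicking the same
#' tissue scanned at different gain/dynamic-range settings.
#'
#' @param block_size Side of the square blocks (pixels, >= 9).
#' @param n_blocks_per_class Physical blocks generated per class; the
#'   default matches the study-scale block collection (about 4000
#'   per-setting observations over 4 settings), and examples pass
#'   smaller explicit counts.
#' @param smoothing Length-2 vector of Gaussian smoothing SDs (pixels),
#'   one per class (IDC first, BM second).
#' @param gains Per-setting multiplicative gains (> 0).
#' @param gammas Per-setting compression exponents (> 0).
#' @param seed Integer seed.
#' @return Object of class `image_gen_spec`.
#' @export
image_gen_spec <- function(block_size = 23L, n_blocks_per_class = 500L,
                           smoothing = c(1, 3),
                           gains = c(1, 1.15, 0.9, 1.25),
                           gammas = c(1, 0.8, 1.2, 0.7),
                           seed = 1L) {
  stopifnot(
    block_size >= 9, n_blocks_per_class >= 1,
    length(smoothing) == 2, all(smoothing > 0),
    length(gains) == length(gammas), all(gains > 0), all(gammas > 0)
  )
  structure(list(
    block_size = as.integer(block_size),
    n_blocks_per_class = as.integer(n_blocks_per_class),
    smoothing = smoothing,
    gains = gains,
    gammas = gammas,
    seed = as.integer(seed)
  ), class = "image_gen_spec")
}

# Separable Gaussian smoothing with reflected edges.
gaussian_smooth <- function(x, sigma) {
  r <- max(1L, ceiling(3 * sigma))
  k <- stats::dnorm(-r:r, sd = sigma)
  k <- k / sum(k)
  smooth_rows <- function(m) {
    n <- nrow(m)
    pad <- rbind(m[rev(seq_len(r)), , drop = FALSE], m,
                 m[n:(n - r + 1), , drop = FALSE])
    out <- matrix(0, n, ncol(m))
    for (i in seq_along(k)) {
      out <- out + k[i] * pad[i:(i + n - 1), , drop = FALSE]
    }
    out
  }
  t(smooth_rows(t(smooth_rows(x))))
}

#' Generate a synthetic paired multi-setting texture dataset
#'
#' @param spec An [image_gen_spec()].
#' @return List with `blocks` (list indexed by setting, each a list of
#'   8-bit integer matrices), `masks` (matching full-coverage 0/1
#'   matrices) and `manifest` (data.frame with `sample_id`, `setting_id`,
#'   `pair_id`, `class`).  Deterministic for a fixed seed.
#' @export
generate_texture_dataset <- function(spec) {
  stopifnot(inherits(spec, "image_gen_spec"))
  bs <- spec$block_size
  n_settings <- length(spec$gains)
  classes <- factor(rep(c("IDC", "BM"), each = spec$n_blocks_per_class),
                    levels = c("IDC", "BM"))
  n_pairs <- length(classes)

  bases <- with_seed(spec$seed, {
    lapply(seq_len(n_pairs), function(p) {
      sigma <- spec$smoothing[as.integer(classes[p])]
      b <- gaussian_smooth(matrix(stats::rnorm(bs * bs), bs, bs), sigma)
      (b - min(b)) / (max(b) - min(b)) # to [0, 1]
    })
  })

  blocks <- lapply(seq_len(n_settings), function(st) {
    lapply(bases, function(b) {
      u <- matrix(pmin(1, spec$gains[st] * b), nrow(b), ncol(b))
      img <- round(255 * u^spec$gammas[st])
      storage.mode(img) <- "integer"
      img
    })
  })
  mask <- matrix(1L, bs, bs)
  manifest <- do.call(rbind, lapply(seq_len(n_settings), function(st) {
    data.frame(
      sample_id = sprintf("S%d_P%d", st, seq_len(n_pairs)),
      setting_id = st,
      pair_id = seq_len(n_pairs),
      class = classes,
      stringsAsFactors = FALSE
    )
  }))
  rownames(manifest) <- NULL
  list(blocks = blocks, masks = replicate(n_pairs, mask, simplify = FALSE),
       manifest = manifest)
}

#' Write a synthetic texture dataset to disk as pipeline input
#'
#' Writes one grayscale PNG per block plus a matching all-inside mask
#' PNG, and a `manifest.csv` in the dialect [run_extract()] reads
#' (`sample_id, setting_id, pair_id, class, image, mask`).  The PNG
#' round trip is lossless for 8-bit data.
#'
#' @param dataset Output of [generate_texture_dataset()].
#' @param dir Writable directory (created if absent).
#' @return The manifest data.frame (with file paths), invisibly.
#' @export
write_fixtures <- function(dataset, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  manifest <- dataset$manifest
  n_settings <- length(dataset$blocks)
  manifest$image <- NA_character_
  manifest$mask <- NA_character_
  for (i in seq_len(nrow(manifest))) {
    st <- manifest$setting_id[i]
    p <- manifest$pair_id[i]
    img_path <- file.path(dir, sprintf("block_s%d_p%03d.png", st, p))
    png::writePNG(dataset$blocks[[st]][[p]] / 255, img_path)
    manifest$image[i] <- img_path
    mask_path <- file.path(dir, sprintf("mask_p%03d.png", p))
    if (!file.exists(mask_path)) {
      png::writePNG(dataset$masks[[p]] * 1.0, mask_path)
    }
    manifest$mask[i] <- mask_path
  }
  manifest_path <- file.path(dir, "manifest.csv")
  utils::write.csv(manifest, manifest_path, row.names = FALSE)
  invisible(manifest)
}
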