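#' Read an 8-bit grayscale image as an integer matrix
#'
#' Supports PNG (always) and TIFF (when the \pkg{tiff} package is
#' available).  Multi-channel images are reduced to their first channel.
#'
#' @param path File path ending in `.png`, `.tif` or `.tiff`.
#' @return Integer matrix with values in `0..255`.
#' @export
read_gray_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  x <- if (ext == "png") {
    png::readPNG(path)
  } else if (ext %in% c("tif", "tiff")) {
    if (!requireNamespace("tiff", quietly = TRUE)) {
      stop_invalid("reading ", path, " requires the 'tiff' package")
    }
    tiff::readTIFF(path)
  } else {
    stop_invalid("unsupported image format: ", path)
  }
  if (length(dim(x)) == 3) x <- x[, , 1]
  img <- round(x * 255)
  storage.mode(img) <- "integer"
  img
}

#' Extract feature-table rows from ROI images
#'
#' Tiles each masked region of interest into non-overlapping
#' `block_size` x `block_size` blocks (left-to-right, top-to-bottom from
#' the top-left corner), keeps only tiles fully covered by the mask, and
#' extracts the 126-feature vector from each.  When an input image has
#' more than one tile, tile coordinates are appended to `sample_id` and
#' `pair_id` so that tiles at the same position remain paired across
#' settings.
#'
#' @param manifest Data.frame (or path to a CSV) with columns
#'   `sample_id`, `setting_id`, `pair_id`, `class`, `image`, `mask`.
#' @param cfg A [texture_config()].
#' @param block_size Tile side in pixels.
#' @return A labeled feature table: one row per fully covered tile with
#'   columns `sample_id`, `setting_id`, `pair_id`, `class`,
#'   `F1`..`F126`.
#' @export
run_extract <- function(manifest, cfg = texture_config(), block_size = 23L) {
  if (is.character(manifest)) {
    manifest <- utils::read.csv(manifest, stringsAsFactors = FALSE)
  }
  out <- vector("list", nrow(manifest))
  for (i in seq_len(nrow(manifest))) {
    img <- read_gray_image(manifest$image[i])
    mask <- read_gray_image(manifest$mask[i])
    if (!all(dim(img) == dim(mask))) {
      stop_invalid("image/mask size mismatch for ", manifest$image[i])
    }
    tiles <- list()
    n_br <- nrow(img) %/% block_size
    n_bc <- ncol(img) %/% block_size
    for (br in seq_len(n_br) - 1L) {
      for (bc in seq_len(n_bc) - 1L) {
        rr <- br * block_size + seq_len(block_size)
        cc <- bc * block_size + seq_len(block_size)
        if (all(mask[rr, cc] != 0)) {
          fv <- extract_features(img[rr, cc, drop = FALSE], cfg)
          suffix <- if (n_br * n_bc > 1L) sprintf("_b%d_%d", br, bc) else ""
          tiles[[length(tiles) + 1L]] <- data.frame(
            sample_id = paste0(manifest$sample_id[i], suffix),
            setting_id = manifest$setting_id[i],
            pair_id = paste0(manifest$pair_id[i], suffix),
            class = manifest$class[i],
            as.data.frame(t(fv)),
            stringsAsFactors = FALSE
          )
        }
      }
    }
    if (length(tiles) == 0L) {
      warning("no fully covered tiles in ", manifest$image[i])
      next
    }
    out[[i]] <- do.call(rbind, tiles)
  }
  res <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  if (is.null(res)) {
    res <- data.frame(sample_id = character(), setting_id = integer(),
                      pair_id = character(), class = character())
  }
  rownames(res) <- NULL
  res
}

#' Pipeline configuration
#'
#' @param texture A [texture_config()].
#' @param svm An [svm_config()].
#' @param ga A [ga_params()].
#' @param top_n Features kept on each filter list.
#' @param pool_floor Minimum candidate-pool size before the union
#'   fallback engages.
#' @param cardinalities Subset sizes the wrapper is run for.
#' @param split_fraction Fraction of pairs used for selection (the rest
#'   is held out for testing).
#' @param seed Global seed (drives the split; the GA and folds have
#'   their own recorded seeds).
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(texture = texture_config(),
                            svm = svm_config(), ga = ga_params(),
                            top_n = 40L, pool_floor = 5L,
                            cardinalities = c(5L, 10L, 15L),
                            split_fraction = 0.5, seed = 1L) {
  stopifnot(split_fraction > 0, split_fraction < 1)
  structure(list(texture = texture, svm = svm, ga = ga,
                 top_n = as.integer(top_n),
                 pool_floor = as.integer(pool_floor),
                 cardinalities = as.integer(cardinalities),
                 split_fraction = split_fraction,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Split a feature table into selection and test halves by pair
#'
#' Pairs (physical blocks) are assigned as whole units - every setting's
#' observation of a pair lands on the same side - stratified by class, so
#' no information leaks from the selection half into the held-out half.
#'
#' @param table Labeled feature table.
#' @param fraction Fraction of pairs assigned to the selection half.
#' @param seed Integer seed.
#' @return List with `selection`, `test` (data.frames) and
#'   `selection_pairs`, `test_pairs`.
#' @export
split_pairs <- function(table, fraction = 0.5, seed = 1L) {
  pairs <- unique(table[, c("pair_id", "class")])
  sel_pairs <- with_seed(seed, {
    unlist(lapply(split(pairs$pair_id, pairs$class), function(p) {
      resample(p, round(length(p) * fraction))
    }), use.names = FALSE)
  })
  sel <- table$pair_id %in% sel_pairs
  list(
    selection = table[sel, , drop = FALSE],
    test = table[!sel, , drop = FALSE],
    selection_pairs = sel_pairs,
    test_pairs = setdiff(pairs$pair_id, sel_pairs)
  )
}

# Per-setting list(x, y) over the given feature columns.
setting_data_list <- function(table, features) {
  settings <- sort(unique(table$setting_id))
  stats::setNames(lapply(settings, function(s) {
    rows <- table$setting_id == s
    list(x = as.matrix(table[rows, features, drop = FALSE]),
         y = factor(table$class[rows]))
  }), paste0("setting_", settings))
}

#' Summary statistics of a set of per-setting accuracies
#'
#' @param accuracies Numeric vector of per-setting accuracies.
#' @return List with `mean`, `sd` (sample SD), `min` and `max`.
#' @export
accuracy_summary <- function(accuracies) {
  list(mean = mean(accuracies), sd = stats::sd(accuracies),
       min = min(accuracies), max = max(accuracies))
}

#' Run the full universal feature selection on a feature table
#'
#' Splits the pairs 50/50 (or per `split_fraction`) into a selection and
#' a test half; standardizes features on the selection half and reapplies
#' the scaling to the test half; scores all features with the three
#' filter metrics and builds the candidate pool; runs the GA wrapper once
#' per requested cardinality on the selection half; and finally trains
#' one SVM per setting on the selection half with each chosen subset and
#' reports its accuracy on the held-out half.
#'
#' @param table Labeled feature table.
#' @param config A [pipeline_config()].
#' @return Object of class `run_report`: list with elements `pool`
#'   (candidate pool), `scores`, `selections` (one per cardinality, each
#'   with chosen features, per-setting CV and held-out accuracies and
#'   their summaries), `split` (pair ids per half) and `config`.
#' @export
run_select <- function(table, config = pipeline_config()) {
  check_feature_table(table)
  features <- feature_columns(table)
  halves <- split_pairs(table, config$split_fraction, config$seed)
  scaling <- scale_features(halves$selection, features)
  sel_scaled <- scaling$table
  test_scaled <- apply_scaling(halves$test, scaling)

  scores <- compute_filter_scores(sel_scaled)
  pool <- build_candidate_pool(scores, sel_scaled, config$top_n,
                               config$svm, config$pool_floor)
  sel_data <- setting_data_list(sel_scaled, pool$pool)
  test_data <- setting_data_list(test_scaled, pool$pool)

  selections <- lapply(config$cardinalities, function(k) {
    params <- config$ga
    params$cardinality <- min(k, length(pool$pool))
    ga <- ga_evolve(sel_data, params, config$svm)
    sel_feats <- ga$best_features
    holdout <- vapply(names(sel_data), function(s) {
      fit <- svm_train(
        sel_data[[s]]$x[, sel_feats, drop = FALSE],
        sel_data[[s]]$y, config$svm
      )
      mean(predict(fit, test_data[[s]]$x[, sel_feats, drop = FALSE]) ==
             test_data[[s]]$y)
    }, numeric(1))
    list(
      cardinality = params$cardinality,
      features = sel_feats,
      feature_names = feature_names()[
        as.integer(sub("^F", "", sel_feats))],
      cv_accuracies = ga$best_report$accuracies,
      cv_summary = accuracy_summary(ga$best_report$accuracies),
      holdout_accuracies = holdout,
      holdout_summary = accuracy_summary(holdout),
      fitness = ga$best_report$fitness,
      history = ga$history
    )
  })

  structure(list(
    pool = pool,
    scores = scores,
    selections = selections,
    split = list(selection_pairs = halves$selection_pairs,
                 test_pairs = halves$test_pairs),
    scaling_degenerate = names(scaling$degenerate)[scaling$degenerate],
    config = config
  ), class = "run_report")
}

#' Render a selection run report as text
#'
#' @param report A `run_report` from [run_select()].
#' @return Character vector of report lines (also printed by the
#'   `print` method).
#' @export
render_report <- function(report) {
  lines <- character(0)
  add <- function(...) lines <<- c(lines, paste0(...))
  add("Universal feature selection report")
  add("  candidate pool: ", length(report$pool$pool), " features",
      if (report$pool$fallback_used) " (union fallback)" else "")
  for (sel in report$selections) {
    if (length(sel$features) == 0L) {
      add("  [k=", sel$cardinality, "] no features selected")
      next
    }
    add("  [k=", sel$cardinality, "] selected: ",
        paste(sel$features, collapse = ", "))
    add("      names: ", paste(sel$feature_names, collapse = "; "))
    add("      selection-half CV accuracy per setting: ",
        paste(sprintf("%.4f", sel$cv_accuracies), collapse = ", "))
    add("      held-out accuracy per setting: ",
        paste(sprintf("%.4f", sel$holdout_accuracies), collapse = ", "))
    s <- sel$holdout_summary
    add(sprintf("      held-out mean %.4f sd %.4f (min %.4f, max %.4f)",
                s$mean, s$sd, s$min, s$max))
  }
  lines
}

#' @export
print.run_report <- function(x, ...) {
  cat(render_report(x), sep = "\n")
  invisible(x)
}

#' Write / read a labeled feature table as CSV
#'
#' @param table Labeled feature table.
#' @param path CSV file path.
#' @return `write_feature_table` returns `path` invisibly;
#'   `read_feature_table` returns the table with `class` as a factor.
#' @export
write_feature_table <- function(table, path) {
  utils::write.csv(table, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  out <- utils::read.csv(path, stringsAsFactors = FALSE)
  out$class <- factor(out$class)
  out
}
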