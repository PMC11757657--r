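#' Whole-slide prediction map
#'
#' A prediction map assigns one tissue class (see [tissue_levels()]) to every
#' patch position of a slide tiling. It is the sole interface between the
#' tissue-classification step and everything downstream: patch selection and
#' scoring consume the grid, never pixels, so fixture-generated maps and
#' classifier-generated maps are interchangeable.
#'
#' @param grid Matrix of tissue labels, either character labels or integer
#'   codes 0..3.
#' @param patch_size Pixels per patch edge.
#' @param slide_id Optional slide identifier.
#' @param probs Optional `rows x cols x 3` array of class probabilities for
#'   (PanNET, NNPP, stroma); each tiled patch's triple must sum to 1 within
#'   1e-6.
#' @return Object of class `prediction_map`.
#' @export
prediction_map <- function(grid, patch_size = 256, slide_id = NA_character_,
                           probs = NULL) {
  if (is.character(grid)) {
    grid <- matrix(tissue_code(grid), nrow(grid), ncol(grid))
  }
  if (!is.matrix(grid) || !is.numeric(grid)) {
    abort("`grid` must be a matrix of tissue labels or codes")
  }
  if (!all(grid %in% 0:3)) abort("grid labels must be one of the 4 tissue classes")
  storage.mode(grid) <- "integer"
  attributes(grid) <- list(dim = dim(grid))
  if (!is.null(probs)) {
    if (!identical(dim(probs)[1:2], dim(grid)) || dim(probs)[3] != 3) {
      abort("`probs` must be a rows x cols x 3 array matching the grid")
    }
    sums <- apply(probs, c(1, 2), sum)
    tiled <- grid != tissue_code("background")
    if (any(abs(sums[tiled] - 1) > 1e-6)) {
      abort("per-patch class probabilities must sum to 1 (within 1e-6)")
    }
  }
  structure(
    list(grid = grid, patch_size = as.integer(patch_size),
         slide_id = slide_id, probs = probs),
    class = "prediction_map"
  )
}

#' @export
print.prediction_map <- function(x, ...) {
  counts <- table(factor(tissue_label(x$grid), levels = tissue_levels()))
  cat(sprintf("<prediction_map> %s: %dx%d patches of %d px\n",
              x$slide_id, nrow(x$grid), ncol(x$grid), x$patch_size))
  print(counts)
  invisible(x)
}

#' @method tidy prediction_map
#' @export
tidy.prediction_map <- function(x, ...) {
  grid <- x$grid
  out <- tibble(
    row = as.vector(row(grid)),
    col = as.vector(col(grid)),
    label = factor(tissue_label(as.vector(grid)), levels = tissue_levels())
  )
  if (!is.null(x$probs)) {
    out$p_PanNET <- as.vector(x$probs[, , 1])
    out$p_NNPP <- as.vector(x$probs[, , 2])
    out$p_stroma <- as.vector(x$probs[, , 3])
  }
  dplyr::arrange(out, .data$row, .data$col)
}

#' Read and write prediction maps
#'
#' The on-disk form is a TSV grid of integer codes plus a JSON sidecar
#' (`<prefix>.json`) carrying grid shape, patch size, label legend, slide id
#' and, when present, the per-patch probability triples. The round trip is
#' lossless.
#'
#' @param map A [prediction_map()].
#' @param prefix Path prefix; `<prefix>.tsv` and `<prefix>.json` are written.
#' @return `read_prediction_map()` returns the reconstructed
#'   [prediction_map()].
#' @export
write_prediction_map <- function(map, prefix) {
  stopifnot(inherits(map, "prediction_map"))
  utils::write.table(map$grid, paste0(prefix, ".tsv"), sep = "\t",
                     row.names = FALSE, col.names = FALSE)
  sidecar <- list(
    shape = dim(map$grid), patch_size = map$patch_size,
    slide_id = map$slide_id, legend = tissue_levels()
  )
  if (!is.null(map$probs)) sidecar$probs <- as.vector(map$probs)
  jsonlite::write_json(sidecar, paste0(prefix, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(prefix)
}

#' @rdname write_prediction_map
#' @export
read_prediction_map <- function(prefix) {
  side <- jsonlite::read_json(paste0(prefix, ".json"), simplifyVector = TRUE)
  grid <- as.matrix(utils::read.table(paste0(prefix, ".tsv"), sep = "\t"))
  dimnames(grid) <- NULL
  stopifnot(identical(dim(grid), as.integer(side$shape)))
  probs <- if (!is.null(side$probs)) array(side$probs, c(side$shape, 3))
  prediction_map(grid, patch_size = side$patch_size,
                 slide_id = side$slide_id, probs = probs)
}

luminance <- function(img) {
  if (length(dim(img)) == 3) (img[, , 1] + img[, , 2] + img[, , 3]) / 3 else img
}

#' Tile a slide image into patches
#'
#' Cuts a slide image into non-overlapping `patch_size` tiles on a regular
#' grid (trailing partial tiles are dropped) and keeps only tiles whose
#' tissue fraction reaches `tissue_threshold`. Tissue is defined as non-white
#' pixels (luminance <= 0.9). Positions below the threshold are background.
#'
#' @param img `H x W x 3` (or `H x W`) array with values in `[0, 1]`.
#' @param patch_size Tile edge length in pixels.
#' @param tissue_threshold Minimum tissue fraction for a tile to be emitted.
#' @return Tibble with `row`, `col` (1-based grid coordinates),
#'   `tissue_fraction` and a `patch` list-column of image arrays, with a
#'   `grid_shape` attribute giving the full tiling dimensions.
#' @export
tile_slide <- function(img, patch_size, tissue_threshold = 0.1) {
  d <- dim(img)
  nr <- d[1] %/% patch_size
  nc <- d[2] %/% patch_size
  if (nr < 1 || nc < 1) {
    warn("slide smaller than one patch; returning no tiles")
    out <- tibble(row = integer(), col = integer(),
                  tissue_fraction = numeric(), patch = list())
    attr(out, "grid_shape") <- c(0L, 0L)
    return(out)
  }
  grid <- tidyr::expand_grid(row = seq_len(nr), col = seq_len(nc))
  patches <- purrr::map2(grid$row, grid$col, function(i, j) {
    ri <- (i - 1) * patch_size + seq_len(patch_size)
    cj <- (j - 1) * patch_size + seq_len(patch_size)
    if (length(d) == 3) img[ri, cj, , drop = FALSE] else img[ri, cj, drop = FALSE]
  })
  frac <- purrr::map_dbl(patches, function(p) mean(luminance(p) <= 0.9))
  out <- tibble(row = grid$row, col = grid$col, tissue_fraction = frac,
                patch = patches)
  out <- out[out$tissue_fraction >= tissue_threshold, ]
  if (nrow(out) == 0) warn("no tissue tiles above threshold; all background")
  attr(out, "grid_shape") <- c(nr, nc)
  out
}

# Ruderman lAlphaBeta <-> RGB transforms used for Reinhard colour transfer.
.rgb2lms <- rbind(c(0.3811, 0.5783, 0.0402),
                  c(0.1967, 0.7244, 0.0782),
                  c(0.0241, 0.1288, 0.8444))
.lms2rgb <- solve(.rgb2lms)
.lms2lab <- diag(c(1 / sqrt(3), 1 / sqrt(6), 1 / sqrt(2))) %*%
  rbind(c(1, 1, 1), c(1, 1, -2), c(1, -1, 0))
.lab2lms <- solve(.lms2lab)

rgb_to_lab <- function(img) {
  px <- matrix(img, ncol = 3)
  lms <- pmax(px %*% t(.rgb2lms), 1e-6)
  log10(lms) %*% t(.lms2lab)
}

lab_to_rgb <- function(lab, dims) {
  lms <- 10^(lab %*% t(.lab2lms))
  px <- lms %*% t(.lms2rgb)
  array(pmin(pmax(px, 0), 1), dims)
}

#' Colour statistics of an image in the lAlphaBeta space
#'
#' @param img RGB array with values in `[0, 1]`.
#' @return Object of class `stain_stats`: per-channel means and standard
#'   deviations in the decorrelated log colour space used by Reinhard-style
#'   colour transfer.
#' @export
stain_stats <- function(img) {
  lab <- rgb_to_lab(img)
  structure(list(mean = colMeans(lab), sd = apply(lab, 2, sd)),
            class = "stain_stats")
}

#' Reinhard-style stain normalisation
#'
#' Matches the per-channel mean and standard deviation of the patch to a
#' reference, in the decorrelated lAlphaBeta log colour space, and converts
#' back to RGB clipped to `[0, 1]`. Channels with (near-)zero variance in the
#' input or the reference are passed through unchanged with a warning, so
#' constant-colour patches are left intact. Normalising a patch to its own
#' statistics is an identity up to rounding.
#'
#' @param patch RGB array with values in `[0, 1]`.
#' @param reference A [stain_stats()] object (the target statistics).
#' @return Normalised RGB array of the same shape.
#' @export
normalize_stain <- function(patch, reference) {
  stopifnot(inherits(reference, "stain_stats"))
  if (length(dim(patch)) != 3 || dim(patch)[3] != 3) {
    abort("`patch` must be an RGB array")
  }
  lab <- rgb_to_lab(patch)
  mu <- colMeans(lab); s <- apply(lab, 2, sd)
  out <- lab
  degen <- s < 1e-8 | reference$sd < 1e-8
  if (any(degen)) {
    warn(sprintf("channel(s) %s have (near-)zero variance; passed through",
                 paste(which(degen), collapse = ", ")))
  }
  for (ch in which(!degen)) {
    out[, ch] <- (lab[, ch] - mu[ch]) / s[ch] * reference$sd[ch] +
      reference$mean[ch]
  }
  lab_to_rgb(out, dim(patch))
}

#' Summary colour features of a patch
#'
#' A compact feature vector (per-channel means and standard deviations,
#' luminance statistics and dark-pixel fraction) used by the feature-table
#' tissue classifier.
#'
#' @param patch RGB (or grayscale) array with values in `[0, 1]`.
#' @return Named numeric vector of 9 features.
#' @export
patch_features <- function(patch) {
  has_rgb <- length(dim(patch)) == 3
  ch <- function(k) if (has_rgb) patch[, , k] else patch
  lum <- luminance(patch)
  c(mean_r = mean(ch(1)), mean_g = mean(ch(2)), mean_b = mean(ch(3)),
    sd_r = sd(ch(1)), sd_g = sd(ch(2)), sd_b = sd(ch(3)),
    mean_lum = mean(lum), sd_lum = sd(lum), frac_dark = mean(lum < 0.5))
}

#' @rdname patch_features
#' @param tiles Output of [tile_slide()].
#' @return For `tiles_to_features()`, a tibble with `row`, `col` and the
#'   feature columns.
#' @export
tiles_to_features <- function(tiles) {
  feats <- purrr::map(tiles$patch, patch_features)
  dplyr::bind_cols(tiles[c("row", "col")],
                   as_tibble(do.call(rbind, feats)))
}

#' Train the patch-level tissue classifier
#'
#' Fits a multinomial logistic model on patch feature vectors, with
#' inverse-class-frequency observation weights to counter class imbalance.
#' This feature-table classifier satisfies the tissue-classifier contract
#' (deterministic inference, labels restricted to PanNET / NNPP / stroma)
#' and is the CPU-friendly reference implementation; any model honouring the
#' same `predict` contract can stand in for it.
#'
#' @param data Data frame with a label column and numeric feature columns.
#' @param label_col Name of the label column (default `"label"`).
#' @param seed Integer seed for the fit.
#' @param maxit Maximum optimiser iterations.
#' @return Object of class `tissue_classifier`.
#' @export
train_tissue_classifier <- function(data, label_col = "label", seed = 1L,
                                    maxit = 300) {
  stopifnot(is.data.frame(data), label_col %in% names(data))
  y <- factor(as.character(data[[label_col]]))
  if (nlevels(droplevels(y)) < 2) {
    abort("training data must contain at least 2 tissue classes")
  }
  y <- droplevels(y)
  features <- setdiff(names(data), label_col)
  x <- data[features]
  stopifnot(all(vapply(x, is.numeric, logical(1))))
  freq <- table(y)
  w <- as.numeric(length(y) / (nlevels(y) * freq[y]))
  df <- cbind(data.frame(.label = y), x)
  fit <- withr::with_seed(seed, {
    nnet::multinom(.label ~ ., data = df, weights = w, trace = FALSE,
                   maxit = maxit, MaxNWts = 5000)
  })
  structure(
    list(fit = fit, classes = levels(y), features = features, seed = seed),
    class = "tissue_classifier"
  )
}

#' @export
print.tissue_classifier <- function(x, ...) {
  cat(sprintf("<tissue_classifier> multinomial on %d features; classes: %s\n",
              length(x$features), paste(x$classes, collapse = ", ")))
  invisible(x)
}

#' Classify patch feature rows
#'
#' @param object A classifier honouring the tissue-classifier contract.
#' @param tiles Tibble of tiles with feature columns (and `row`, `col`).
#' @param ... Unused.
#' @return The input tibble with `.pred_label` (factor) and one probability
#'   column per class (`.p_<class>`); probabilities sum to 1 per row.
#' @export
classify_tiles <- function(object, tiles, ...) UseMethod("classify_tiles")

#' @export
classify_tiles.tissue_classifier <- function(object, tiles, ...) {
  newx <- tiles[object$features]
  pr <- predict(object$fit, newdata = newx, type = "probs")
  if (is.null(dim(pr))) pr <- cbind(1 - pr, pr)  # 2-class edge case
  pr <- matrix(as.numeric(pr), nrow = nrow(tiles),
               dimnames = list(NULL, object$classes))
  lab <- object$classes[max.col(pr, ties.method = "first")]
  out <- tiles
  out$.pred_label <- factor(lab, levels = object$classes)
  for (cl in object$classes) out[[paste0(".p_", cl)]] <- pr[, cl]
  out
}

#' Oracle tissue classifier backed by a ground-truth map
#'
#' Returns the fixture's true label at each grid position, with a degenerate
#' probability triple. Used to test that the prediction-map assembly is a
#' pass-through of classifier decisions.
#'
#' @param truth Tissue map matrix (ground truth).
#' @return Object of class `oracle_tissue_classifier`.
#' @export
oracle_tissue_classifier <- function(truth) {
  structure(list(truth = truth, classes = c("PanNET", "NNPP", "stroma")),
            class = "oracle_tissue_classifier")
}

#' @export
classify_tiles.oracle_tissue_classifier <- function(object, tiles, ...) {
  lab <- tissue_label(object$truth[cbind(tiles$row, tiles$col)])
  lab[!lab %in% object$classes] <- "stroma"  # oracle never emits background
  pr <- matrix(0, nrow(tiles), 3, dimnames = list(NULL, object$classes))
  pr[cbind(seq_len(nrow(tiles)), match(lab, object$classes))] <- 1
  out <- tiles
  out$.pred_label <- factor(lab, levels = object$classes)
  for (cl in object$classes) out[[paste0(".p_", cl)]] <- pr[, cl]
  out
}

#' Assemble a prediction map from classified tiles
#'
#' Every tiled position receives the classifier's label; positions absent
#' from `tiles` (below the tissue threshold) stay background.
#'
#' @param classifier Object with a [classify_tiles()] method.
#' @param tiles Tibble of tiles with feature columns, as from
#'   [tiles_to_features()]; its `grid_shape` attribute (or `grid_shape`
#'   argument) gives the tiling dimensions.
#' @param grid_shape `c(rows, cols)` of the tiling; defaults to the
#'   attribute on `tiles`.
#' @param patch_size,slide_id Map metadata.
#' @return A [prediction_map()] with per-patch probability triples.
#' @export
build_prediction_map <- function(classifier, tiles, grid_shape = NULL,
                                 patch_size = 256, slide_id = NA_character_) {
  grid_shape <- grid_shape %||% attr(tiles, "grid_shape")
  if (is.null(grid_shape)) abort("`grid_shape` is required")
  scored <- classify_tiles(classifier, tiles)
  grid <- matrix(tissue_code("background"), grid_shape[1], grid_shape[2])
  probs <- array(NA_real_, c(grid_shape, 3))
  idx <- cbind(scored$row, scored$col)
  grid[idx] <- tissue_code(as.character(scored$.pred_label))
  for (k in 1:3) {
    cl <- c("PanNET", "NNPP", "stroma")[k]
    col <- scored[[paste0(".p_", cl)]]
    if (is.null(col)) col <- as.numeric(scored$.pred_label == cl)
    probs[cbind(idx, k)] <- col
  }
  prediction_map(grid, patch_size = patch_size, slide_id = slide_id,
                 probs = probs)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
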