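# Trainable pixel classification of the neural network versus background:
# a multiscale image-feature bank (the commonly enabled WEKA set) feeding a
# random forest, plus a non-learned Otsu fallback.

#' Compute a multiscale per-pixel feature stack
#'
#' For each scale sigma: Gaussian smoothing, gradient magnitude, Laplacian,
#' the two Hessian eigenvalues, and a difference of Gaussians (sigma vs
#' 2 sigma); the raw intensity is feature 1. Deterministic; reflective
#' borders.
#'
#' @param image numeric matrix.
#' @param scales sorted positive sigmas in pixels.
#' @return A `FeatureStack`: list with `features` (rows x cols x n), ordered
#'   `feature_names`, and `scales`.
#' @export
compute_features <- function(image, scales = c(1, 2, 4, 8)) {
  stopifnot(is.matrix(image), all(scales > 0), !is.unsorted(scales))
  if (max(dim(image)) <= 2 * ceiling(3 * max(scales)) + 1)
    stop("image smaller than filter support")
  feats <- list(original = image)
  for (s in scales) {
    k0 <- gauss_kernel1d(s, 0L)
    k1 <- gauss_kernel1d(s, 1L)
    k2 <- gauss_kernel1d(s, 2L)
    g <- conv_sep(image, k0, k0)
    gr <- conv_sep(image, k1, k0)   # d/drow
    gc <- conv_sep(image, k0, k1)   # d/dcol
    hrr <- conv_sep(image, k2, k0)
    hcc <- conv_sep(image, k0, k2)
    hrc <- conv_sep(image, k1, k1)
    tr <- hrr + hcc
    det_disc <- sqrt(pmax((hrr - hcc)^2 / 4 + hrc^2, 0))
    nm <- function(what) sprintf("%s_s%g", what, s)
    feats[[nm("gauss")]] <- g
    feats[[nm("gradmag")]] <- sqrt(gr^2 + gc^2)
    feats[[nm("laplacian")]] <- tr
    feats[[nm("hess_max")]] <- tr / 2 + det_disc
    feats[[nm("hess_min")]] <- tr / 2 - det_disc
    k0b <- gauss_kernel1d(2 * s, 0L)
    feats[[nm("dog")]] <- g - conv_sep(image, k0b, k0b)
  }
  arr <- array(unlist(feats, use.names = FALSE),
               c(dim(image), length(feats)))
  structure(list(features = arr, feature_names = names(feats),
                 scales = scales), class = "FeatureStack")
}

feature_matrix <- function(fs, idx = NULL) {
  d <- dim(fs$features)
  m <- matrix(fs$features, d[1] * d[2], d[3])
  colnames(m) <- fs$feature_names
  if (!is.null(idx)) m <- m[idx, , drop = FALSE]
  as.data.frame(m)
}

#' Sparse annotations from a reference mask
#'
#' Samples `n_per_class` pixel labels per class from a binary mask -- the
#' programmatic stand-in for interactive scribble annotation when ground
#' truth is available.
#'
#' @param mask logical matrix (TRUE = network class).
#' @param n_per_class pixels sampled per class.
#' @param seed integer seed.
#' @param image index of the annotated image (for multi-image training sets).
#' @return Data frame with columns `image`, `row`, `col`, `class`.
#' @export
annotate_from_mask <- function(mask, n_per_class = 200L, seed = 1L,
                               image = 1L) {
  stopifnot(is.logical(mask))
  fg <- which(mask); bg <- which(!mask)
  if (!length(fg) || !length(bg))
    stop("mask must contain both classes")
  with_seed(seed, {
    pick <- function(pool, cls) {
      i <- sample(pool, min(n_per_class, length(pool)))
      data.frame(image = image, row = (i - 1L) %% nrow(mask) + 1L,
                 col = (i - 1L) %/% nrow(mask) + 1L, class = cls,
                 stringsAsFactors = FALSE)
    }
    rbind(pick(fg, "network"), pick(bg, "background"))
  })
}

#' Train a random-forest pixel classifier
#'
#' WEKA-style trainable segmentation: a probability random forest (default
#' 200 trees, unlimited depth, class-balanced case weights) on the
#' [compute_features()] bank. Trained once per dataset and applied to all
#' fields.
#'
#' @param images a matrix or list of matrices.
#' @param annotations data frame as from [annotate_from_mask()]: columns
#'   `image`, `row`, `col`, `class` (both classes required).
#' @param scales feature scales, as in [compute_features()].
#' @param n_trees number of trees.
#' @param seed integer seed (forest growth is deterministic given it).
#' @return A `PixelClassifier`: list with the ranger `model`,
#'   `feature_names`, `scales`, `classes`, `training_accuracy`.
#' @export
train_classifier <- function(images, annotations, scales = c(1, 2, 4, 8),
                             n_trees = 200L, seed = 1L) {
  if (is.matrix(images)) images <- list(images)
  stopifnot(all(c("image", "row", "col", "class") %in% names(annotations)))
  cls <- sort(unique(annotations$class))
  if (length(cls) < 2L) stop("annotations must cover both classes")
  X <- NULL
  for (im in unique(annotations$image)) {
    ann <- annotations[annotations$image == im, ]
    fs <- compute_features(images[[im]], scales)
    idx <- (ann$col - 1L) * nrow(images[[im]]) + ann$row
    X <- rbind(X, feature_matrix(fs, idx))
  }
  y <- factor(annotations$class, levels = cls)
  w <- 1 / table(y)[y]
  fit <- ranger::ranger(x = X, y = y, num.trees = n_trees,
                        probability = TRUE, seed = seed, num.threads = 1L,
                        case.weights = as.numeric(w))
  pred <- predict(fit, X, num.threads = 1L)$predictions
  acc <- mean(colnames(pred)[max.col(pred, ties.method = "first")] == y)
  structure(list(model = fit, feature_names = colnames(X), scales = scales,
                 classes = cls, n_trees = n_trees, seed = seed,
                 training_accuracy = acc),
            class = "PixelClassifier")
}

#' @export
print.PixelClassifier <- function(x, ...) {
  cat(sprintf("PixelClassifier: %d trees, %d features (sigma %s), training accuracy %.3f\n",
              x$n_trees, length(x$feature_names),
              paste(x$scales, collapse = "/"), x$training_accuracy))
  invisible(x)
}

#' Classify an image into network-probability map
#'
#' @param image numeric matrix.
#' @param classifier a [train_classifier()] model.
#' @return Matrix of network-class probabilities in `[0, 1]`.
#' @export
classify <- function(image, classifier) {
  stopifnot(inherits(classifier, "PixelClassifier"))
  fs <- compute_features(image, classifier$scales)
  if (!identical(fs$feature_names, classifier$feature_names))
    stop("feature descriptor mismatch between image and classifier")
  pr <- predict(classifier$model, feature_matrix(fs), num.threads = 1L)$predictions
  matrix(pr[, "network"], nrow(image), ncol(image))
}

#' Binarize a probability map
#'
#' @param prob probability matrix from [classify()].
#' @param threshold network mask = probability >= threshold.
#' @return Logical mask with a `provenance` attribute.
#' @export
binarize_prob <- function(prob, threshold = 0.5) {
  m <- prob >= threshold
  attr(m, "provenance") <- sprintf("classifier>=%.3g", threshold)
  m
}

#' Automatic (Otsu) threshold segmentation
#'
#' Non-learned fallback and the thresholding step for soma counting.
#'
#' @param image numeric matrix (non-constant).
#' @param method currently `"otsu"`.
#' @return Logical mask; attributes `threshold` (in the image's intensity
#'   scale) and `provenance`.
#' @export
auto_threshold <- function(image, method = "otsu") {
  method <- match.arg(method, "otsu")
  lo <- min(image); hi <- max(image)
  if (hi <= lo) stop("degenerate histogram: constant image")
  thr01 <- EBImage::otsu(EBImage::Image((image - lo) / (hi - lo)),
                         range = c(0, 1), levels = 256L)
  thr <- thr01 * (hi - lo) + lo
  m <- image > thr
  attr(m, "threshold") <- thr
  attr(m, "provenance") <- method
  m
}

#' Save / load a pixel classifier
#'
#' The feature descriptor travels with the model so a mismatch between the
#' classifier and an image's feature bank is detectable at classify time.
#' @param classifier a `PixelClassifier`.
#' @param path file path (RDS).
#' @return `path` / the classifier.
#' @export
save_classifier <- function(classifier, path) {
  stopifnot(inherits(classifier, "PixelClassifier"))
  saveRDS(classifier, path)
  invisible(path)
}

#' @rdname save_classifier
#' @export
load_classifier <- function(path) {
  x <- readRDS(path)
  if (!inherits(x, "PixelClassifier")) stop("not a PixelClassifier file")
  x
}
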