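#' Configuration for the immune-cell pixel segmenter
#'
#' The segmenter is a trainable pixelwise classifier: each pixel is
#' described by multiscale image features (Gaussian smoothings, differences
#' of Gaussians, gradient magnitude and local variance) and classified into
#' the three morphology classes by a random forest. Class semantics are
#' fixed: 1 = dendritic cells and macrophages (elongated, branched),
#' 2 = round-ellipsoid leukocyte-like cells, 3 = background. Unlabeled
#' pixels in the training data are treated as class 3.
#'
#' @param input_size_px images are resampled to this square size before
#'   feature extraction and prediction (bilinear for images, nearest for
#'   labels).
#' @param feature_sigmas Gaussian scales (px) of the feature bank.
#' @param n_trees random-forest size.
#' @param pixels_per_image training pixels sampled per image (stratified by
#'   class).
#' @param val_fraction fraction of training images held out for the
#'   training report's Dice estimate.
#' @param seed integer seed controlling sampling and forest growth.
#' @return An object of class `segmenter_config`.
#' @export
segmenter_config <- function(input_size_px = 256, feature_sigmas = c(1, 2, 4, 8),
                             n_trees = 200, pixels_per_image = 3000,
                             val_fraction = 0.2, seed = 1L) {
  stopifnot(input_size_px > 0, n_trees > 0, pixels_per_image > 0,
            length(feature_sigmas) > 0, val_fraction >= 0, val_fraction < 1)
  structure(list(input_size_px = as.integer(input_size_px),
                 feature_sigmas = feature_sigmas, n_trees = as.integer(n_trees),
                 pixels_per_image = as.integer(pixels_per_image),
                 val_fraction = val_fraction, seed = as.integer(seed)),
            class = "segmenter_config")
}

#' Train the 3-class immune-cell segmenter
#'
#' @param images list of numeric `H x W` intensity matrices.
#' @param labelmaps list of integer label maps (values in 1:3; same length
#'   as `images`). Unlabeled conventions should be encoded as class 3
#'   before calling.
#' @param config a [segmenter_config].
#' @return An object of class `immune_segmenter` carrying the fitted forest
#'   and a `report` with the out-of-bag error and, when a validation split
#'   exists, per-class and macro Dice on held-out images.
#' @export
train_segmenter <- function(images, labelmaps, config = segmenter_config()) {
  stopifnot(length(images) >= 1, length(images) == length(labelmaps))
  for (lm in labelmaps)
    if (!all(lm %in% 1:3)) stop("labels must take values in {1, 2, 3}")
  set.seed(config$seed)
  n <- length(images)
  n_val <- floor(config$val_fraction * n)
  val_idx <- if (n_val > 0) sample(n, n_val) else integer(0)
  train_idx <- setdiff(seq_len(n), val_idx)
  if (length(train_idx) == 0) train_idx <- seq_len(n)

  feat <- list(); lab <- list()
  for (i in train_idx) {
    f <- pixel_features(resample_image(images[[i]], config$input_size_px),
                        config$feature_sigmas)
    l <- resample_labels(labelmaps[[i]], config$input_size_px)
    sel <- stratified_pixel_sample(as.vector(l), config$pixels_per_image)
    feat[[length(feat) + 1]] <- f[sel, , drop = FALSE]
    lab[[length(lab) + 1]] <- as.vector(l)[sel]
  }
  X <- do.call(rbind, feat)
  y <- factor(unlist(lab), levels = 1:3)
  fit <- ranger::ranger(x = X, y = y, num.trees = config$n_trees,
                        seed = config$seed, num.threads = 1)
  seg <- structure(list(forest = fit, config = config, trained = TRUE),
                   class = "immune_segmenter")
  report <- list(oob_error = fit$prediction.error)
  if (length(val_idx) > 0) {
    dices <- lapply(val_idx, function(i) {
      pred <- segment_immune_cells(images[[i]], seg)
      truth <- resample_labels(labelmaps[[i]], config$input_size_px)
      multiclass_dice(pred, truth)
    })
    report$val_macro_dice <- mean(vapply(dices, `[[`, numeric(1), "macro"))
    report$val_per_class_dice <- colMeans(do.call(rbind, lapply(dices, `[[`, "per_class")))
  }
  seg$report <- report
  seg
}

#' Predict the 3-class label map of an image
#'
#' @param image numeric `H x W` intensity matrix.
#' @param segmenter a trained [train_segmenter] model.
#' @return Integer label map of size `input_size_px x input_size_px` with
#'   values in 1:3.
#' @export
segment_immune_cells <- function(image, segmenter) {
  if (!inherits(segmenter, "immune_segmenter") || !isTRUE(segmenter$trained))
    stop("segmenter is not trained")
  size <- segmenter$config$input_size_px
  f <- pixel_features(resample_image(image, size), segmenter$config$feature_sigmas)
  pred <- predict(segmenter$forest, data = f, num.threads = 1)$predictions
  matrix(as.integer(as.character(pred)), size, size)
}

#' Immune-cell density features from a label map
#'
#' @param labels integer label map with values in 1:3.
#' @return List with `myeloid_area_pct` (class 1), `leukocyte_area_pct`
#'   (class 2) and `total_inflammation_pct` (their sum), as percentages of
#'   all pixels.
#' @export
inflammation_densities <- function(labels) {
  if (!all(labels %in% 1:3)) stop("labels must take values in {1, 2, 3}")
  n <- length(labels)
  myeloid <- 100 * sum(labels == 1) / n
  leuko <- 100 * sum(labels == 2) / n
  list(myeloid_area_pct = myeloid, leukocyte_area_pct = leuko,
       total_inflammation_pct = myeloid + leuko)
}

#' Per-class and macro-averaged Dice of two label maps
#'
#' One-vs-rest Dice per class; a class absent from both maps scores 1.
#'
#' @param pred,truth integer label maps of identical shape, values in 1:3.
#' @return List with `per_class` (named numeric of length 3) and `macro`.
#' @export
multiclass_dice <- function(pred, truth) {
  if (!identical(dim(pred), dim(truth))) stop("label maps must have identical shape")
  per_class <- vapply(1:3, function(k) {
    a <- pred == k; b <- truth == k
    denom <- sum(a) + sum(b)
    if (denom == 0) 1 else 2 * sum(a & b) / denom
  }, numeric(1))
  names(per_class) <- c("dendritic_macrophage", "leukocyte_like", "background")
  list(per_class = per_class, macro = mean(per_class))
}

# ---- internal ---------------------------------------------------------------

resample_image <- function(img, size) {
  if (all(dim(img) == size)) return(img)
  EBImage::resize(img, w = size, h = size)
}

resample_labels <- function(labels, size) {
  if (all(dim(labels) == size)) return(labels)
  H <- nrow(labels); W <- ncol(labels)
  ri <- pmin(pmax(round(seq(1, H, length.out = size)), 1), H)
  ci <- pmin(pmax(round(seq(1, W, length.out = size)), 1), W)
  labels[ri, ci, drop = FALSE]
}

# multiscale feature bank; one row per pixel
pixel_features <- function(img, sigmas) {
  blurs <- lapply(sigmas, function(s) EBImage::gblur(img, sigma = s))
  feats <- c(list(raw = as.vector(img)),
             stats::setNames(lapply(blurs, as.vector),
                             sprintf("gauss_%g", sigmas)))
  for (k in seq_len(length(sigmas) - 1))
    feats[[sprintf("dog_%g_%g", sigmas[k], sigmas[k + 1])]] <-
      as.vector(blurs[[k]] - blurs[[k + 1]])
  g1 <- blurs[[1]]
  feats$grad_mag <- as.vector(sqrt(grad_y(g1)^2 + grad_x(g1)^2))
  mu <- EBImage::gblur(img, sigma = 2)
  feats$local_sd <- as.vector(sqrt(pmax(EBImage::gblur(img^2, sigma = 2) - mu^2, 0)))
  do.call(cbind, feats)
}

stratified_pixel_sample <- function(labels, n_total) {
  classes <- sort(unique(labels))
  per <- ceiling(n_total / length(classes))
  unlist(lapply(classes, function(k) {
    idx <- which(labels == k)
    if (length(idx) <= per) idx else sample(idx, per)
  }))
}
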