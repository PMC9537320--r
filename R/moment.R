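#' Morphometric features of a single-cell image
#'
#' A compact descriptor used by the fast classifier backend and by tests of
#' the synthetic generator: per-channel intensity means and standard
#' deviations, the nucleus area fraction, and the axis ratio of an ellipse
#' fitted to the nucleus mask by second-order image moments. The nucleus is
#' taken to be the darkest-quartile pixels of the blue-dominance map, which
#' matches both the synthetic renders and Romanowsky-type stains where the
#' nucleus is the most chromatic structure.
#'
#' @param image a [cell_image()].
#' @return named numeric vector of features.
#' @export
image_features <- function(image) {
  stopifnot(inherits(image, "cell_image"))
  px <- image$pixels
  lum <- (px[, , 1] + px[, , 2] + px[, , 3]) / 3
  mask <- nucleus_mask(px)
  ar <- mask_axis_ratio(mask)
  c(mean_r = mean(px[, , 1]), mean_g = mean(px[, , 2]), mean_b = mean(px[, , 3]),
    sd_r = stats::sd(px[, , 1]), sd_g = stats::sd(px[, , 2]),
    sd_b = stats::sd(px[, , 3]),
    sd_lum = stats::sd(lum),
    nucleus_frac = mean(mask),
    axis_ratio = ar,
    nucleus_spread = mask_spread(mask))
}

# darkest-luminance pixels, thresholded midway between the (noise-trimmed)
# darkest and brightest intensities; the nucleus is the darkest structure
nucleus_mask <- function(px) {
  lum <- (px[, , 1] + px[, , 2] + px[, , 3]) / 3
  thr <- (stats::quantile(lum, 0.01) + stats::quantile(lum, 0.99)) / 2
  lum < thr
}

#' Axis ratio of the ellipse fitted to a mask by second moments
#'
#' The ratio of the major to the minor axis of the ellipse with the same
#' second-order central moments as the mask — the quantity morphological
#' grading criteria use to separate consecutive granulocyte maturation
#' stages (e.g. a round nucleus vs one elongated beyond 3:1).
#'
#' @param mask logical matrix.
#' @return axis ratio `>= 1` (1 for an empty or degenerate mask).
#' @export
mask_axis_ratio <- function(mask) {
  idx <- which(mask, arr.ind = TRUE)
  if (nrow(idx) < 4L) return(1)
  cc <- scale(idx, scale = FALSE)
  ev <- eigen(crossprod(cc) / nrow(cc), symmetric = TRUE, only.values = TRUE)$values
  ev <- pmax(ev, 1e-9)
  sqrt(ev[1] / ev[2])
}

# normalized RMS radius of the mask, sensitive to lobe separation
mask_spread <- function(mask) {
  idx <- which(mask, arr.ind = TRUE)
  if (nrow(idx) < 4L) return(0)
  cc <- scale(idx, scale = FALSE)
  sqrt(mean(rowSums(cc^2))) / sqrt(nrow(idx))
}

#' Build the fast feature-based classifier backend
#'
#' Multinomial logistic regression on [image_features()], fitted with
#' \code{nnet::multinom}. It honors the same contract as the convolutional
#' reference model — [train_round()] / [predict_proba()] — and exists so
#' pool and selection logic can be exercised quickly; the network remains
#' the reference classifier.
#'
#' @param classes optional class-name vector fixing the label order.
#' @return a classifier handle of class `moment_classifier`.
#' @export
build_moment_classifier <- function(classes = NULL) {
  structure(list(fit = NULL, classes = classes, feature_scale = NULL,
                 training_log = NULL, rounds_trained = 0L),
            class = "moment_classifier")
}

#' @export
print.moment_classifier <- function(x, ...) {
  cat("moment_classifier:",
      if (is.null(x$fit)) "untrained" else paste(length(x$classes), "classes"), "\n")
  invisible(x)
}

#' @rdname build_moment_classifier
#' @param model a `moment_classifier` handle.
#' @param images list of training [cell_image()]s.
#' @param labels their labels.
#' @param config a [train_config()]; the fit is a full refit each round
#'   (`epochs` sets the optimizer's iteration budget), logged as one row.
#' @param warm_start start optimization from the previous round's
#'   coefficients when possible.
#' @param validation optional list(`images`, `labels`) scored for the log.
#' @param ... unused.
#' @export
train_round.moment_classifier <- function(model, images, labels, config,
                                          warm_start = TRUE, validation = NULL,
                                          ...) {
  stopifnot(inherits(config, "train_config"), length(images) == length(labels))
  if (is.null(model$classes)) model$classes <- sort(unique(labels))
  absent <- setdiff(model$classes, labels)
  if (length(absent))
    warning("class(es) absent from training data: ", paste(absent, collapse = ", "))
  feats <- t(vapply(images, image_features, numeric(10)))
  ctr <- colMeans(feats)
  scl <- pmax(apply(feats, 2, stats::sd), 1e-8)
  model$feature_scale <- list(center = ctr, scale = scl)
  df <- data.frame(scale(feats, ctr, scl))
  df$.label <- factor(labels, levels = model$classes)
  wts <- if (warm_start && !is.null(model$fit)) model$fit$wts else NULL
  fit <- with_seed(config$seed, suppressWarnings(tryCatch(
    nnet::multinom(.label ~ ., data = df, trace = FALSE,
                   maxit = max(100L, config$epochs), decay = 1e-3, Wts = wts),
    error = function(e)
      nnet::multinom(.label ~ ., data = df, trace = FALSE,
                     maxit = max(100L, config$epochs), decay = 1e-3))))
  model$fit <- fit
  train_acc <- mean(as.character(stats::predict(fit, df)) == labels)
  val_acc <- NA_real_
  if (!is.null(validation)) {
    vp <- predict_proba(model, validation$images)
    val_acc <- mean(predicted_labels(vp) == validation$labels)
  }
  model$training_log <- data.frame(epoch = seq_len(config$epochs),
                                   train_accuracy = train_acc,
                                   validation_accuracy = val_acc)
  model$rounds_trained <- model$rounds_trained + 1L
  model
}

#' @rdname build_moment_classifier
#' @export
predict_proba.moment_classifier <- function(model, images, ...) {
  if (is.null(model$fit)) stop("moment classifier is untrained")
  feats <- t(vapply(images, image_features, numeric(10)))
  df <- data.frame(scale(feats, model$feature_scale$center,
                         model$feature_scale$scale))
  p <- stats::predict(model$fit, df, type = "probs")
  if (is.null(dim(p))) {  # two-class fits return a vector
    p <- cbind(1 - p, p)
  }
  if (length(images) == 1L) p <- matrix(p, nrow = 1L)
  colnames(p) <- model$classes
  p <- p / rowSums(p)
  prediction_matrix(vapply(images, `[[`, character(1), "id"), p)
}
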