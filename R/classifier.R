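#' Pluggable probabilistic classifier contract
#'
#' All pool and selection logic is backend-agnostic: any object implementing
#' `train_round()` and `predict_proba()` can drive the semi-supervised loop.
#' The package ships two backends — the convolutional reference model of
#' [build_reference_model()] and the fast feature-based
#' [build_moment_classifier()] used where network training would be overkill.
#'
#' @param model a classifier handle.
#' @param ... passed to methods.
#' @name classifier-contract
NULL

#' @rdname classifier-contract
#' @export
train_round <- function(model, ...) UseMethod("train_round")

#' @rdname classifier-contract
#' @export
predict_proba <- function(model, ...) UseMethod("predict_proba")

#' Training configuration for one semi-supervised round
#'
#' @param epochs passes over the teacher data (reference protocol: 250).
#' @param learning_rate SGD step size; the reference protocol uses 0.01 for
#'   the first round and 0.005 for warm-started later rounds.
#' @param momentum SGD momentum coefficient (0.9).
#' @param batch_size minibatch size (32).
#' @param seed RNG seed for shuffling and augmentation draws.
#' @param augment apply the rotate/flip/shift recipe to every training image.
#' @return a `train_config` list.
#' @export
train_config <- function(epochs = 250L, learning_rate = 0.01, momentum = 0.9,
                         batch_size = 32L, seed = 1L, augment = TRUE) {
  stopifnot(epochs >= 1L, learning_rate > 0, learning_rate < 1,
            momentum >= 0, batch_size >= 1L)
  structure(list(epochs = as.integer(epochs), learning_rate = learning_rate,
                 momentum = momentum, batch_size = as.integer(batch_size),
                 seed = as.integer(seed), augment = isTRUE(augment)),
            class = "train_config")
}

#' Build the convolutional reference classifier
#'
#' An 8-layer convolutional network in four stages: each stage applies two
#' 3x3 convolutions, each followed by batch normalization and ReLU, then a
#' squeeze-and-excitation block that re-weights the stage's channels from
#' their globally pooled statistics, then 2x2 max pooling. Global average
#' pooling and a softmax head of width `n_classes` follow the last stage.
#' Weights use seeded He initialization. The input side length must be a
#' multiple of 16 and at least 32 so the four pooling stages leave a
#' non-trivial spatial map.
#'
#' @param input_size input image side length in pixels (default 282).
#' @param n_classes number of output classes (>= 2).
#' @param seed integer seed for weight initialization.
#' @param channels convolution widths of the four stages.
#' @param se_reduction bottleneck reduction ratio of the SE blocks.
#' @param classes optional class-name vector (length `n_classes`) fixing the
#'   label order; otherwise set at the first training call.
#' @return a classifier handle of class `se_cnn`.
#' @export
build_reference_model <- function(input_size = 282L, n_classes, seed = 1L,
                                  channels = c(32L, 64L, 128L, 256L),
                                  se_reduction = 16L, classes = NULL) {
  input_size <- as.integer(input_size)
  if (input_size < 32L || input_size %% 16L != 0L)
    stop("input_size must be a multiple of 16 and at least 32 ",
         "(four 2x2 pooling stages); got ", input_size)
  stopifnot(n_classes >= 2L, length(channels) == 4L)
  if (!is.null(classes) && length(classes) != n_classes)
    stop("classes must have length n_classes")
  he <- function(nr, nc, fan_in) matrix(stats::rnorm(nr * nc, 0, sqrt(2 / fan_in)), nr, nc)
  params <- list(); state <- list()
  with_seed(seed, {
    cin <- 3L
    for (s in 1:4) {
      cs <- channels[s]
      cr <- max(1L, cs %/% se_reduction)
      params[[paste0("conv", s, "a_w")]] <- he(9L * cin, cs, 9L * cin)
      params[[paste0("conv", s, "a_b")]] <- numeric(cs)
      params[[paste0("bn", s, "a_g")]] <- rep(1, cs)
      params[[paste0("bn", s, "a_b")]] <- numeric(cs)
      params[[paste0("conv", s, "b_w")]] <- he(9L * cs, cs, 9L * cs)
      params[[paste0("conv", s, "b_b")]] <- numeric(cs)
      params[[paste0("bn", s, "b_g")]] <- rep(1, cs)
      params[[paste0("bn", s, "b_b")]] <- numeric(cs)
      params[[paste0("se", s, "_w1")]] <- he(cs, cr, cs)
      params[[paste0("se", s, "_b1")]] <- numeric(cr)
      params[[paste0("se", s, "_w2")]] <- he(cr, cs, cr)
      params[[paste0("se", s, "_b2")]] <- numeric(cs)
      state[[paste0("bn", s, "a_mean")]] <- numeric(cs)
      state[[paste0("bn", s, "a_var")]] <- rep(1, cs)
      state[[paste0("bn", s, "b_mean")]] <- numeric(cs)
      state[[paste0("bn", s, "b_var")]] <- rep(1, cs)
      cin <- cs
    }
    params$head_w <- he(channels[4], n_classes, channels[4])
    params$head_b <- numeric(n_classes)
  })
  structure(
    list(params = params, state = state,
         velocity = lapply(params, function(p) p * 0),
         input_size = input_size, n_classes = as.integer(n_classes),
         channels = as.integer(channels), classes = classes,
         training_log = NULL, rounds_trained = 0L),
    class = "se_cnn")
}

#' @export
print.se_cnn <- function(x, ...) {
  n_par <- sum(vapply(x$params, length, integer(1)))
  cat(sprintf("se_cnn: input %dpx, %d classes, channels %s, %s parameters\n",
              x$input_size, x$n_classes, paste(x$channels, collapse = "/"),
              format(n_par, big.mark = ",")))
  invisible(x)
}

secnn_forward <- function(model, x, training) {
  p <- model$params; st <- model$state
  caches <- list()
  for (s in 1:4) {
    for (half in c("a", "b")) {
      cw <- p[[paste0("conv", s, half, "_w")]]
      cb <- p[[paste0("conv", s, half, "_b")]]
      cf <- conv3_forward(x, cw, cb)
      caches[[paste0("conv", s, half)]] <- cf$cache
      bkey <- paste0("bn", s, half)
      bf <- bn_forward(cf$out, p[[paste0(bkey, "_g")]], p[[paste0(bkey, "_b")]],
                       st[[paste0(bkey, "_mean")]], st[[paste0(bkey, "_var")]],
                       training)
      caches[[bkey]] <- bf$cache
      if (training) {
        st[[paste0(bkey, "_mean")]] <- bf$run_mean
        st[[paste0(bkey, "_var")]] <- bf$run_var
      }
      rf <- relu_forward(bf$out)
      caches[[paste0("relu", s, half)]] <- rf$cache
      x <- rf$out
    }
    sf <- se_forward(x, p[[paste0("se", s, "_w1")]], p[[paste0("se", s, "_b1")]],
                     p[[paste0("se", s, "_w2")]], p[[paste0("se", s, "_b2")]])
    caches[[paste0("se", s)]] <- sf$cache
    mf <- maxpool2_forward(sf$out)
    caches[[paste0("pool", s)]] <- mf$cache
    x <- mf$out
  }
  gf <- gap_forward(x)
  caches$gap <- gf$cache
  df <- dense_forward(gf$out, p$head_w, p$head_b)
  caches$head <- df$cache
  list(logits = df$out, caches = caches, state = st)
}

secnn_backward <- function(model, caches, dlogits) {
  g <- list()
  db <- dense_backward(dlogits, caches$head)
  g$head_w <- db$dweight; g$head_b <- db$dbias
  dx <- gap_backward(db$dx, caches$gap)
  for (s in 4:1) {
    dx <- maxpool2_backward(dx, caches[[paste0("pool", s)]])
    sb <- se_backward(dx, caches[[paste0("se", s)]])
    g[[paste0("se", s, "_w1")]] <- sb$dw1; g[[paste0("se", s, "_b1")]] <- sb$db1
    g[[paste0("se", s, "_w2")]] <- sb$dw2; g[[paste0("se", s, "_b2")]] <- sb$db2
    dx <- sb$dx
    for (half in c("b", "a")) {
      dx <- relu_backward(dx, caches[[paste0("relu", s, half)]])
      bkey <- paste0("bn", s, half)
      bb <- bn_backward(dx, caches[[bkey]])
      g[[paste0(bkey, "_g")]] <- bb$dgamma; g[[paste0(bkey, "_b")]] <- bb$dbeta
      cb <- conv3_backward(bb$dx, caches[[paste0("conv", s, half)]])
      g[[paste0("conv", s, half, "_w")]] <- cb$dweight
      g[[paste0("conv", s, half, "_b")]] <- cb$dbias
      dx <- cb$dx
    }
  }
  g
}

# stack a list of cell_images into an (H, W, 3, N) batch array
stack_images <- function(images, input_size) {
  n <- length(images)
  x <- array(0, c(input_size, input_size, 3L, n))
  for (i in seq_len(n)) {
    px <- images[[i]]$pixels
    if (dim(px)[1] != input_size || dim(px)[2] != input_size)
      stop("image '", images[[i]]$id, "' is ", dim(px)[1], "x", dim(px)[2],
           " but the model expects ", input_size, "x", input_size)
    x[, , , i] <- px
  }
  x
}

#' Train the reference model for one round
#'
#' Runs seeded SGD-with-momentum over the labeled images for
#' `config$epochs` epochs of shuffled minibatches, applying the
#' rotate/flip/shift augmentation to every training image when
#' `config$augment` is set. With `warm_start = TRUE` (transfer learning
#' across rounds) optimization continues from the handle's current weights;
#' otherwise weights are freshly re-initialized from `config$seed`.
#'
#' @param model an `se_cnn` handle.
#' @param images list of [cell_image()] training images.
#' @param labels character vector of their labels.
#' @param config a [train_config()].
#' @param warm_start continue from the current weights (default `TRUE`).
#' @param validation optional list with elements `images` and `labels`,
#'   scored (over training classes) once per epoch for the training log.
#' @param ... unused.
#' @return the trained handle; `$training_log` holds one row per epoch with
#'   `train_accuracy` and `validation_accuracy`.
#' @export
train_round.se_cnn <- function(model, images, labels, config,
                               warm_start = TRUE, validation = NULL, ...) {
  stopifnot(inherits(config, "train_config"), length(images) == length(labels),
            length(images) > 0L)
  if (is.null(model$classes))
    model$classes <- sort(unique(labels))
  bad <- setdiff(labels, model$classes)
  if (length(bad))
    stop("labels outside the model's classes: ", paste(unique(bad), collapse = ", "))
  absent <- setdiff(model$classes, labels)
  if (length(absent))
    warning("class(es) absent from training data: ", paste(absent, collapse = ", "))
  if (!warm_start) {
    fresh <- build_reference_model(model$input_size, model$n_classes,
                                   seed = config$seed, channels = model$channels,
                                   classes = model$classes)
    model$params <- fresh$params
    model$state <- fresh$state
    model$velocity <- fresh$velocity
  }
  y <- match(labels, model$classes)
  n <- length(images)
  log_rows <- vector("list", config$epochs)
  with_seed(config$seed + model$rounds_trained, {
    for (ep in seq_len(config$epochs)) {
      ord <- sample.int(n)
      correct <- 0L
      for (start in seq(1L, n, by = config$batch_size)) {
        idx <- ord[start:min(start + config$batch_size - 1L, n)]
        batch <- images[idx]
        if (config$augment) batch <- lapply(batch, augment_image)
        x <- stack_images(batch, model$input_size)
        fw <- secnn_forward(model, x, training = TRUE)
        model$state <- fw$state
        lo <- softmax_xent(fw$logits, y[idx])
        correct <- correct + sum(max.col(t(lo$probs), ties.method = "first") == y[idx])
        grads <- secnn_backward(model, fw$caches, lo$dlogits)
        for (k in names(grads)) {
          model$velocity[[k]] <- config$momentum * model$velocity[[k]] -
            config$learning_rate * grads[[k]]
          model$params[[k]] <- model$params[[k]] + model$velocity[[k]]
        }
      }
      val_acc <- NA_real_
      if (!is.null(validation)) {
        vp <- predict_proba(model, validation$images)
        val_acc <- mean(predicted_labels(vp) == validation$labels)
      }
      log_rows[[ep]] <- data.frame(epoch = ep, train_accuracy = correct / n,
                                   validation_accuracy = val_acc)
    }
  })
  model$training_log <- do.call(rbind, log_rows)
  model$rounds_trained <- model$rounds_trained + 1L
  model
}

#' @describeIn build_reference_model class probabilities for a batch of
#'   images; deterministic (no augmentation, batch statistics frozen).
#' @param images list of [cell_image()] to score.
#' @param batch_size scoring batch size.
#' @param ... unused.
#' @param model an `se_cnn` handle.
#' @export
predict_proba.se_cnn <- function(model, images, batch_size = 64L, ...) {
  if (is.null(model$classes))
    stop("model has no class names yet; train it or pass classes= at build time")
  n <- length(images)
  probs <- matrix(0, n, model$n_classes, dimnames = list(NULL, model$classes))
  for (start in seq_len_by(n, batch_size)) {
    idx <- start:min(start + batch_size - 1L, n)
    x <- stack_images(images[idx], model$input_size)
    fw <- secnn_forward(model, x, training = FALSE)
    probs[idx, ] <- t(softmax_cols(fw$logits))
  }
  prediction_matrix(vapply(images, `[[`, character(1), "id"), probs)
}

seq_len_by <- function(n, by) if (n == 0L) integer(0) else seq(1L, n, by = by)

#' Argmax labels of a prediction matrix
#' @param preds a [prediction_matrix()].
#' @return character vector of predicted class names (ties to lowest index).
#' @export
predicted_labels <- function(preds) {
  stopifnot(inherits(preds, "prediction_matrix"))
  colnames(preds$probs)[max.col(preds$probs, ties.method = "first")]
}

#' Gate a model on held-out validation accuracy
#'
#' The semi-supervised loop only starts once the initial model reaches a
#' minimum validation accuracy (80% in the reference protocol, inclusive).
#' Accuracy is scored over evaluation classes when a taxonomy with a merge
#' map is supplied.
#'
#' @param model a classifier handle.
#' @param images list of labeled validation [cell_image()]s.
#' @param labels their labels (training-class names).
#' @param min_accuracy pass threshold, a fraction (default 0.80).
#' @param taxonomy optional [label_taxonomy()]; when given, predictions and
#'   truths are merged onto evaluation classes before scoring.
#' @return list with `pass` (logical) and `accuracy`.
#' @export
validation_gate <- function(model, images, labels, min_accuracy = 0.80,
                            taxonomy = NULL) {
  if (length(images) == 0L) stop("validation set is empty")
  stopifnot(length(images) == length(labels))
  preds <- predicted_labels(predict_proba(model, images))
  truth <- labels
  if (!is.null(taxonomy)) {
    preds <- merge_labels(preds, taxonomy)
    truth <- merge_labels(truth, taxonomy)
  }
  acc <- mean(preds == truth)
  list(pass = acc >= min_accuracy, accuracy = acc)
}
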