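# A deliberately tiny network configuration keeps these tests fast; the
# architecture (8 conv layers, BN, SE blocks, 4 pooling stages) is identical
# to the full-width model.
tiny_net <- function(n_classes = 3, seed = 7, classes = NULL) {
  build_reference_model(32, n_classes, seed = seed,
                        channels = c(2L, 3L, 2L, 3L), se_reduction = 2L,
                        classes = classes)
}

test_that("analytic gradients match finite differences", {
  ns <- asNamespace("sslcyto")
  m <- tiny_net(classes = c("a", "b", "c"))
  set.seed(42)
  x <- array(runif(32 * 32 * 3 * 2), c(32, 32, 3, 2))
  y <- c(1L, 3L)
  fw <- ns$secnn_forward(m, x, training = TRUE)
  lo <- ns$softmax_xent(fw$logits, y)
  grads <- ns$secnn_backward(m, fw$caches, lo$dlogits)
  loss_at <- function(model) {
    f <- ns$secnn_forward(model, x, training = TRUE)
    ns$softmax_xent(f$logits, y)$loss
  }
  eps <- 1e-5
  # conv biases sit in front of batchnorm, so their true gradient is ~0;
  # check representative weight, scale and SE parameters instead
  for (k in c("conv1a_w", "conv3b_w", "bn2a_g", "bn4b_b", "se2_w1",
              "se3_w2", "head_w", "head_b")) {
    p <- m$params[[k]]
    for (j in sample(length(p), min(2, length(p)))) {
      m2 <- m; m2$params[[k]][j] <- p[j] + eps
      m3 <- m; m3$params[[k]][j] <- p[j] - eps
      num <- (loss_at(m2) - loss_at(m3)) / (2 * eps)
      expect_equal(grads[[k]][j], num, tolerance = 1e-4,
                   label = paste("gradient of", k))
    }
  }
})

test_that("model construction enforces the pooling-compatible input size", {
  expect_error(build_reference_model(30, 6), "multiple of 16")
  expect_error(build_reference_model(16, 6), "at least 32")
  m <- build_reference_model(32, 6, channels = c(2L, 2L, 2L, 2L))
  expect_s3_class(m, "se_cnn")
})

test_that("identical seeds give identical initial predictions", {
  imgs <- small_synth()[1:4]
  m1 <- tiny_net(seed = 5, classes = c("a", "b", "c"))
  m2 <- tiny_net(seed = 5, classes = c("a", "b", "c"))
  expect_identical(predict_proba(m1, imgs)$probs, predict_proba(m2, imgs)$probs)
  m3 <- tiny_net(seed = 6, classes = c("a", "b", "c"))
  expect_false(identical(predict_proba(m3, imgs)$probs,
                         predict_proba(m1, imgs)$probs))
})

test_that("predictions are normalized, deterministic and shape-checked", {
  imgs <- small_synth()[1:6]
  m <- tiny_net(classes = c("a", "b", "c"))
  p1 <- predict_proba(m, imgs)
  expect_true(all(abs(rowSums(p1$probs) - 1) < 1e-6))
  expect_true(all(is.finite(p1$probs)))
  expect_identical(p1$probs, predict_proba(m, imgs)$probs)
  empty <- predict_proba(m, list())
  expect_equal(nrow(empty$probs), 0)
  small <- cell_image("tiny", array(0.5, c(8, 8, 3)))
  expect_error(predict_proba(m, list(small)), "expects 32")
})

test_that("training improves accuracy on separable synthetic classes", {
  imgs <- small_synth()
  labs <- vapply(imgs, `[[`, character(1), "true_label")
  m <- build_reference_model(32, 3, seed = 2, channels = c(4L, 8L, 8L, 16L),
                             se_reduction = 4L, classes = sort(unique(labs)))
  cfg <- train_config(epochs = 12, learning_rate = 0.02, batch_size = 36,
                      seed = 3, augment = TRUE)
  m <- train_round(m, imgs, labs, cfg, warm_start = FALSE)
  log <- m$training_log
  expect_equal(nrow(log), 12)
  expect_gt(log$train_accuracy[12], log$train_accuracy[1])
})

test_that("a warm start resumes from trained weights", {
  imgs <- small_synth()
  labs <- vapply(imgs, `[[`, character(1), "true_label")
  m <- build_reference_model(32, 3, seed = 2, channels = c(4L, 8L, 8L, 16L),
                             se_reduction = 4L, classes = sort(unique(labs)))
  cfg <- train_config(epochs = 30, learning_rate = 0.02, batch_size = 12,
                      seed = 3, augment = FALSE)
  trained <- train_round(m, imgs, labs, cfg, warm_start = FALSE,
                         validation = list(images = imgs, labels = labs))
  cfg1 <- train_config(epochs = 1, learning_rate = 0.005, batch_size = 12,
                       seed = 4, augment = FALSE)
  warm <- train_round(trained, imgs, labs, cfg1, warm_start = TRUE,
                      validation = list(images = imgs, labels = labs))
  cold <- train_round(m, imgs, labs, cfg1, warm_start = FALSE,
                      validation = list(images = imgs, labels = labs))
  expect_gte(warm$training_log$validation_accuracy[1],
             cold$training_log$validation_accuracy[1])
  expect_equal(nrow(warm$training_log), 1)
})

test_that("training warns when a class has no examples", {
  imgs <- small_synth()
  labs <- vapply(imgs, `[[`, character(1), "true_label")
  keep <- labs != "trilobed"
  m <- tiny_net(classes = sort(unique(labs)))
  cfg <- train_config(epochs = 1, learning_rate = 0.01, seed = 1)
  expect_warning(train_round(m, imgs[keep], labs[keep], cfg, warm_start = FALSE),
                 "trilobed")
})

test_that("the validation gate is inclusive at its threshold", {
  # stub classifier scoring exactly 8 of 10 images correct
  ids <- sprintf("v%02d", 1:10)
  probs <- matrix(rep(c(0.9, 0.1), 10), 10, 2, byrow = TRUE,
                  dimnames = list(ids, c("pos", "neg")))
  probs[9:10, ] <- rep(c(0.1, 0.9), each = 2)
  truth <- rep("pos", 10)
  imgs <- lapply(ids, function(i) cell_image(i, array(0.5, c(8, 8, 3))))
  g <- validation_gate(stub_model(probs), imgs, truth, min_accuracy = 0.80)
  expect_true(g$pass)          # 80.0% or more passes
  expect_equal(g$accuracy, 0.8)
  expect_false(validation_gate(stub_model(probs), imgs, truth, 0.81)$pass)
  expect_error(validation_gate(stub_model(probs), list(), character(0)), "empty")
})

test_that("gate accuracy is scored over merged evaluation classes", {
  tx <- label_taxonomy(c("bare", "art"), c(bare = "debris", art = "debris"))
  ids <- c("x1", "x2")
  probs <- matrix(c(0.1, 0.9, 0.9, 0.1), 2, byrow = TRUE,
                  dimnames = list(ids, c("bare", "art")))
  imgs <- lapply(ids, function(i) cell_image(i, array(0.5, c(8, 8, 3))))
  # predictions are the "wrong" training class but the same evaluation class
  g <- validation_gate(stub_model(probs), imgs, c("bare", "art"),
                       min_accuracy = 1, taxonomy = tx)
  expect_true(g$pass)
})
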