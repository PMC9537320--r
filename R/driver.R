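#' Experiment configuration
#'
#' Collects every knob of the semi-supervised loop. Reference values follow
#' the bone-marrow protocol: 25 rounds of 250 epochs, a 25-per-class seed
#' pool, 50-per-class validation and test sets, a 5000-image unlabeled
#' subsample per round, a 1000-per-class balancing cap, an 80% validation
#' gate, and learning rates 0.01 (first round) / 0.005 (warm-started later
#' rounds). The confirmation threshold defaults to 0.99 when confirmed
#' self-training runs alone and 0.9 inside the combined strategy, matching
#' the protocol's two settings.
#'
#' @param strategy `"cst"`, `"al"` or `"cst_al"`.
#' @param rounds number of semi-supervised rounds (25).
#' @param epochs_per_round training epochs per round (250).
#' @param initial_per_class seed images per class (25).
#' @param validation_per_class labeled validation images per class (50).
#' @param test_per_class held-out test images per class (50).
#' @param unlabeled_sample_size unlabeled subsample per round (5000).
#' @param per_class_cap balancing cap (1000).
#' @param cst_threshold confirmation-route confidence threshold.
#' @param margin_threshold labeling-route margin threshold (0.2).
#' @param validation_gate minimum validation accuracy before the loop
#'   starts (0.80).
#' @param gate_retries reseeded initial-training attempts before aborting (3).
#' @param lr_first,lr_later learning rates for the first and later rounds.
#' @param momentum,batch_size,augment SGD and augmentation settings.
#' @param backend `"se_cnn"` (convolutional reference model) or `"moment"`
#'   (fast feature-based backend).
#' @param input_size image side length in pixels.
#' @param channels stage widths of the reference model.
#' @param se_reduction SE-block reduction ratio of the reference model.
#' @param seed master seed; every per-round random draw derives from it.
#' @param output_dir optional directory for history CSV, pool snapshots and
#'   training logs.
#' @return an `experiment_config` list.
#' @export
experiment_config <- function(strategy = c("cst_al", "cst", "al"),
                              rounds = 25L, epochs_per_round = 250L,
                              initial_per_class = 25L,
                              validation_per_class = 50L,
                              test_per_class = 50L,
                              unlabeled_sample_size = 5000L,
                              per_class_cap = 1000L,
                              cst_threshold = NULL, margin_threshold = 0.2,
                              validation_gate = 0.80, gate_retries = 3L,
                              lr_first = 0.01, lr_later = 0.005,
                              momentum = 0.9, batch_size = 32L,
                              augment = TRUE,
                              backend = c("se_cnn", "moment"),
                              input_size = 282L,
                              channels = c(32L, 64L, 128L, 256L),
                              se_reduction = 16L,
                              seed = 1L, output_dir = NULL) {
  strategy <- match.arg(strategy)
  backend <- match.arg(backend)
  if (is.null(cst_threshold))
    cst_threshold <- if (strategy == "cst") 0.99 else 0.9
  stopifnot(rounds >= 1L, epochs_per_round >= 1L, initial_per_class >= 1L,
            unlabeled_sample_size >= 1L, per_class_cap >= 1L,
            cst_threshold > 0.5, cst_threshold <= 1,
            margin_threshold > 0, margin_threshold < 1,
            validation_gate > 0, validation_gate <= 1)
  structure(list(strategy = strategy, rounds = as.integer(rounds),
                 epochs_per_round = as.integer(epochs_per_round),
                 initial_per_class = as.integer(initial_per_class),
                 validation_per_class = as.integer(validation_per_class),
                 test_per_class = as.integer(test_per_class),
                 unlabeled_sample_size = as.integer(unlabeled_sample_size),
                 per_class_cap = as.integer(per_class_cap),
                 cst_threshold = cst_threshold,
                 margin_threshold = margin_threshold,
                 validation_gate = validation_gate,
                 gate_retries = as.integer(gate_retries),
                 lr_first = lr_first, lr_later = lr_later,
                 momentum = momentum, batch_size = as.integer(batch_size),
                 augment = isTRUE(augment), backend = backend,
                 input_size = as.integer(input_size),
                 channels = as.integer(channels),
                 se_reduction = as.integer(se_reduction),
                 seed = as.integer(seed), output_dir = output_dir),
            class = "experiment_config")
}

#' Read an experiment configuration from YAML
#'
#' The YAML keys mirror [experiment_config()] argument names.
#'
#' @param path YAML file path.
#' @param ... overrides passed on to [experiment_config()].
#' @return an `experiment_config`.
#' @export
read_experiment_config <- function(path, ...) {
  vals <- yaml::read_yaml(path)
  override <- list(...)
  vals[names(override)] <- override
  do.call(experiment_config, vals)
}

# per-round derived seeds: arms sharing a master seed see identical
# unlabeled subsamples, enabling paired arm comparisons
derive_seeds <- function(master, rounds) {
  with_seed(master, list(sample = sample.int(2^31 - 2L, rounds),
                         balance = sample.int(2^31 - 2L, rounds),
                         train = sample.int(2^31 - 2L, rounds)))
}

#' Assemble a synthetic experiment
#'
#' Generates images for the given class specs and splits them per class
#' into seed, validation, test and unlabeled subsets according to the
#' configuration, plus the identity-merge taxonomy over the spec names.
#'
#' @param specs list of [synth_class_spec()]s.
#' @param config an [experiment_config()].
#' @param unlabeled_per_class unlabeled images generated per class.
#' @return list with `images` (named list), `taxonomy`, `seed_by_class`,
#'   `validation` (`ids`, `labels`), `test` (`ids`, `labels`),
#'   `unlabeled` (an [unlabeled_pool()]).
#' @export
prepare_synthetic_experiment <- function(specs, config, unlabeled_per_class = 60L) {
  n_total <- config$initial_per_class + config$validation_per_class +
    config$test_per_class + unlabeled_per_class
  imgs <- generate_dataset(specs, n_total, config$input_size, seed = config$seed)
  store <- stats::setNames(imgs, vapply(imgs, `[[`, character(1), "id"))
  labs <- vapply(imgs, `[[`, character(1), "true_label")
  ids_by_class <- split(names(store), labs)
  seed_by_class <- list(); val_ids <- character(0); test_ids <- character(0)
  unl_ids <- character(0)
  for (cl in names(ids_by_class)) {
    ids <- ids_by_class[[cl]]
    i1 <- config$initial_per_class
    i2 <- i1 + config$validation_per_class
    i3 <- i2 + config$test_per_class
    seed_by_class[[cl]] <- ids[seq_len(i1)]
    val_ids <- c(val_ids, ids[(i1 + 1):i2])
    test_ids <- c(test_ids, ids[(i2 + 1):i3])
    if (i3 < length(ids)) unl_ids <- c(unl_ids, ids[(i3 + 1):length(ids)])
  }
  truth <- function(ids) vapply(store[ids], `[[`, character(1), "true_label")
  list(images = store,
       taxonomy = label_taxonomy(sort(names(ids_by_class))),
       seed_by_class = seed_by_class,
       validation = list(ids = val_ids, labels = unname(truth(val_ids))),
       test = list(ids = test_ids, labels = unname(truth(test_ids))),
       unlabeled = unlabeled_pool(unl_ids))
}

build_backend <- function(config, taxonomy) {
  cls <- taxonomy$training_classes
  if (config$backend == "se_cnn")
    build_reference_model(config$input_size, length(cls), seed = config$seed,
                          channels = config$channels,
                          se_reduction = config$se_reduction, classes = cls)
  else
    build_moment_classifier(classes = cls)
}

select_additions <- function(strategy, preds, config, oracle) {
  switch(strategy,
         cst = confirm_candidates(cst_candidates(preds, config$cst_threshold),
                                  oracle),
         al = label_queries(margin_candidates(preds, config$margin_threshold),
                            oracle),
         cst_al = combined_selection(preds, config$cst_threshold,
                                     config$margin_threshold, oracle))
}

#' Run one strategy arm of the semi-supervised experiment
#'
#' Executes the full loop: initial training on the seed pool (gated on
#' validation accuracy, with reseeded retries), then per round — subsample
#' the unlabeled pool, score it with the current model, select candidates
#' by the configured strategy, put them to the oracle, move the approved
#' additions into the labeled pool, rebuild the class-balanced training set
#' (newest additions protected, earlier rounds capped), retrain with a warm
#' start, and score the held-out test set. The labeled pool only grows;
#' the balancing cap shapes each round's training set. Images the oracle
#' rejects stay unlabeled and may be resampled in later rounds; only added
#' images leave the unlabeled pool.
#'
#' @param config an [experiment_config()].
#' @param data experiment data as from [prepare_synthetic_experiment()]:
#'   `images`, `taxonomy`, `seed_by_class`, `validation`, `test`,
#'   `unlabeled`.
#' @param oracle an oracle handle (see [make_simulated_oracle()]).
#' @param model optional pre-built classifier handle; defaults to the
#'   configured backend.
#' @return a [round_history()] for this arm (arm name = strategy), with
#'   per-class cumulative counts and, as attribute `"log"`, one structured
#'   row per round (candidate counts, additions, pool reconciliation,
#'   train-set size, gate status).
#' @export
run_experiment <- function(config, data, oracle, model = NULL) {
  stopifnot(inherits(config, "experiment_config"))
  taxonomy <- data$taxonomy
  store <- data$images
  seeds <- derive_seeds(config$seed, config$rounds)
  teacher <- init_teacher_pool(data$seed_by_class, config$initial_per_class,
                               config$per_class_cap)
  unlabeled <- data$unlabeled
  if (is.null(model)) model <- build_backend(config, taxonomy)
  val_imgs <- store[data$validation$ids]
  test_imgs <- store[data$test$ids]

  pool_images <- function(pool) store[pool$records$image_id]
  pool_labels <- function(pool) pool$records$label
  test_accuracy <- function(m) {
    preds <- predicted_labels(predict_proba(m, test_imgs))
    mean(merge_labels(preds, taxonomy) ==
           merge_labels(data$test$labels, taxonomy))
  }

  # initial training, gated on validation accuracy
  gate <- NULL
  for (attempt in seq_len(max(1L, config$gate_retries))) {
    cfg1 <- train_config(config$epochs_per_round, config$lr_first,
                         config$momentum, config$batch_size,
                         seed = seeds$train[1] + attempt - 1L,
                         augment = config$augment)
    model_try <- train_round(model, unname(pool_images(teacher)),
                             pool_labels(teacher), cfg1, warm_start = FALSE,
                             validation = list(images = unname(val_imgs),
                                               labels = data$validation$labels))
    gate <- validation_gate(model_try, unname(val_imgs),
                            data$validation$labels, config$validation_gate,
                            taxonomy)
    model <- model_try
    if (gate$pass) break
  }
  if (!gate$pass)
    stop(sprintf(
      "validation gate not passed after %d attempt(s): accuracy %.3f < %.3f",
      config$gate_retries, gate$accuracy, config$validation_gate))

  hist_rows <- list(); log_rows <- list(); pcc_rows <- list()
  record <- function(n, acc, extra) {
    hist_rows[[n]] <<- data.frame(arm = config$strategy, round = n,
                                  accuracy = acc,
                                  data_count = pool_size(teacher))
    cc <- class_counts(teacher)
    pcc_rows[[n]] <<- data.frame(arm = config$strategy, round = n,
                                 class = names(cc), count = unname(cc))
    log_rows[[n]] <<- extra
    if (!is.null(config$output_dir)) {
      rd <- file.path(config$output_dir, sprintf("round_%02d", n))
      dir.create(rd, showWarnings = FALSE, recursive = TRUE)
      write_pool_csv(teacher, file.path(rd, "teacher_pool.csv"))
      if (!is.null(model$training_log))
        utils::write.csv(model$training_log,
                         file.path(rd, "training_log.csv"), row.names = FALSE)
    }
  }
  record(1L, test_accuracy(model),
         data.frame(round = 1L, sampled = 0L, candidates = 0L, additions = 0L,
                    train_size = pool_size(teacher),
                    gate_accuracy = gate$accuracy, reconciled = TRUE))

  for (n in seq_len(config$rounds)[-1L]) {
    if (pool_size(unlabeled) == 0L) {
      warning("unlabeled pool exhausted at round ", n, "; stopping early")
      break
    }
    sub <- sample_unlabeled(unlabeled, config$unlabeled_sample_size,
                            seed = seeds$sample[n])
    preds <- predict_proba(model, unname(store[sub$ids]))
    additions <- select_additions(config$strategy, preds, config, oracle)
    size_before <- pool_size(teacher)
    upd <- apply_additions(teacher, unlabeled, additions, round = n)
    teacher <- upd$teacher
    unlabeled <- upd$unlabeled
    reconciled <- pool_size(teacher) == size_before + nrow(additions)
    train_pool <- balance_classes(teacher, config$per_class_cap,
                                  newest_round = n, seed = seeds$balance[n])
    cfgn <- train_config(config$epochs_per_round, config$lr_later,
                         config$momentum, config$batch_size,
                         seed = seeds$train[n], augment = config$augment)
    model <- train_round(model, unname(pool_images(train_pool)),
                         pool_labels(train_pool), cfgn, warm_start = TRUE,
                         validation = list(images = unname(val_imgs),
                                           labels = data$validation$labels))
    record(n, test_accuracy(model),
           data.frame(round = n, sampled = pool_size(sub),
                      candidates = nrow(additions), additions = nrow(additions),
                      train_size = pool_size(train_pool),
                      gate_accuracy = NA_real_, reconciled = reconciled))
  }

  history <- round_history(do.call(rbind, hist_rows),
                           per_class_counts = do.call(rbind, pcc_rows),
                           n_classes = length(taxonomy$training_classes))
  attr(history, "log") <- do.call(rbind, log_rows)
  if (!is.null(config$output_dir)) {
    dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
    write_history_csv(history, file.path(config$output_dir, "history.csv"))
    utils::write.csv(attr(history, "log"),
                     file.path(config$output_dir, "round_log.csv"),
                     row.names = FALSE)
  }
  history
}

#' Compare strategy arms
#'
#' Joins per-arm histories into one table (the published table's layout),
#' computes growth statistics of each arm's total count series, and — when
#' per-class counts are available — each arm's per-class share of added
#' images, which shows where a strategy concentrates its additions (margin
#' sampling favours ambiguous classes).
#'
#' @param histories list of single-arm [round_history()] objects with
#'   identical round coverage.
#' @param initial_per_class divisor for the relative increase rate (25).
#' @param output_dir optional; writes `comparison.csv` and a trajectory
#'   plot `comparison.png`.
#' @return list with `history` (joint [round_history()]), `summary`
#'   ([summarize_history()] rows), `growth` (per-arm [growth_statistics()]
#'   of the total counts) and `class_shares` (per-arm data.frame or NULL).
#' @export
compare_arms <- function(histories, initial_per_class = 25,
                         output_dir = NULL) {
  stopifnot(length(histories) >= 1L)
  rounds <- lapply(histories, function(h) sort(unique(h$table$round)))
  if (length(unique(vapply(rounds, length, integer(1)))) != 1L ||
      !all(vapply(rounds, identical, logical(1), rounds[[1]])))
    stop("arms cover different rounds; cannot compare")
  tab <- do.call(rbind, lapply(histories, `[[`, "table"))
  pcc <- do.call(rbind, lapply(histories, `[[`, "per_class_counts"))
  joint <- round_history(tab, per_class_counts = pcc,
                         n_classes = histories[[1]]$n_classes)
  growth <- lapply(split(tab, tab$arm), function(sub)
    growth_statistics(sub$data_count[order(sub$round)], initial_per_class))
  shares <- NULL
  if (!is.null(pcc)) {
    final <- pcc[pcc$round == max(pcc$round), ]
    added <- stats::aggregate(count ~ arm + class, final, sum)
    tot <- stats::aggregate(count ~ arm, added, sum)
    added$share <- added$count / tot$count[match(added$arm, tot$arm)]
    shares <- added
  }
  if (!is.null(output_dir)) {
    dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
    write_history_csv(joint, file.path(output_dir, "comparison.csv"))
    grDevices::png(file.path(output_dir, "comparison.png"), 900, 450)
    op <- graphics::par(mfrow = c(1, 2))
    arms <- unique(tab$arm)
    cols <- seq_along(arms)
    acc <- sapply(arms, function(a) tab$accuracy[tab$arm == a][order(tab$round[tab$arm == a])])
    cnt <- sapply(arms, function(a) tab$data_count[tab$arm == a][order(tab$round[tab$arm == a])])
    graphics::matplot(acc, type = "l", lty = 1, col = cols,
                      xlab = "round", ylab = "test accuracy")
    graphics::legend("bottomright", legend = arms, col = cols, lty = 1)
    graphics::matplot(cnt, type = "l", lty = 1, col = cols,
                      xlab = "round", ylab = "teacher-pool size")
    graphics::par(op)
    grDevices::dev.off()
  }
  list(history = joint, summary = summarize_history(joint),
       growth = growth, class_shares = shares)
}
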