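# Shared fixtures, built in code at load time.

# random probability matrix with Dirichlet-distributed rows
random_prob_matrix <- function(n, k, alpha = 0.3, classes = paste0("c", seq_len(k))) {
  g <- matrix(stats::rgamma(n * k, shape = alpha), n, k)
  p <- g / rowSums(g)
  colnames(p) <- classes
  p
}

# truth-lookup oracle over fabricated ids (no pixels needed: the simulated
# examiner reads only id and true_label)
oracle_for <- function(ids, truths, error_rate = 0, reject_rate = 0, seed = 1L) {
  imgs <- Map(function(i, t) list(id = i, true_label = t), ids, truths)
  make_simulated_oracle(imgs, error_rate = error_rate,
                        reject_rate = reject_rate, seed = seed)
}

# stub classifier emitting a fixed prediction matrix, to exercise the
# backend-agnostic contract without any training
stub_model <- function(probs_by_id) {
  structure(list(probs_by_id = probs_by_id), class = "stub_model")
}

predict_proba.stub_model <- function(model, images, ...) {
  ids <- vapply(images, `[[`, character(1), "id")
  prediction_matrix(ids, model$probs_by_id[ids, , drop = FALSE])
}

train_round.stub_model <- function(model, images, labels, config, ...) model

registerS3method("predict_proba", "stub_model", predict_proba.stub_model,
                 envir = asNamespace("sslcyto"))
registerS3method("train_round", "stub_model", train_round.stub_model,
                 envir = asNamespace("sslcyto"))

# memoized small synthetic image set shared across test files
synth_cache <- new.env(parent = emptyenv())
small_synth <- function() {
  if (is.null(synth_cache$imgs)) {
    specs <- default_class_specs()[c(1, 3, 6)]
    synth_cache$imgs <- generate_dataset(specs, 12, 32, seed = 99)
  }
  synth_cache$imgs
}

# desk-scale experiment pieces with the fast backend
desk_config <- function(strategy = "cst_al", seed = 11L, backend = "moment",
                        rounds = 3L, epochs = 3L) {
  experiment_config(strategy = strategy, rounds = rounds,
                    epochs_per_round = epochs, initial_per_class = 10L,
                    validation_per_class = 8L, test_per_class = 8L,
                    unlabeled_sample_size = 120L, per_class_cap = 1000L,
                    backend = backend, input_size = 32L,
                    channels = c(4L, 8L, 8L, 16L), batch_size = 32L,
                    seed = seed)
}
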