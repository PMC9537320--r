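# Driver tests use the fast feature-based backend; the convolutional
# reference model is exercised end-to-end in the acceptance suite.

desk_data <- function(cfg, specs = default_class_specs(), unlabeled_per_class = 30L) {
  prepare_synthetic_experiment(specs, cfg, unlabeled_per_class = unlabeled_per_class)
}

test_that("a desk-scale run produces a well-formed, reconciled history", {
  cfg <- desk_config("cst_al", seed = 11)
  data <- desk_data(cfg)
  orc <- make_simulated_oracle(data$images, seed = cfg$seed)
  h <- run_experiment(cfg, data, orc)
  expect_s3_class(h, "round_history")
  expect_equal(nrow(h$table), 3)
  expect_true(all(diff(h$table$data_count) >= 0))
  expect_equal(h$table$data_count[1], 60)  # 6 classes x 10 seeds
  log <- attr(h, "log")
  expect_true(all(log$reconciled))
  expect_true(all(log$train_size <= h$table$data_count))
  # per-class cumulative counts sum to the pool size each round
  pcc <- h$per_class_counts
  sums <- tapply(pcc$count, pcc$round, sum)
  expect_equal(as.vector(sums), h$table$data_count)
})

test_that("identical seeds reproduce the history exactly", {
  run_once <- function() {
    cfg <- desk_config("cst", seed = 21)
    data <- desk_data(cfg)
    orc <- make_simulated_oracle(data$images, seed = cfg$seed)
    run_experiment(cfg, data, orc)
  }
  h1 <- run_once(); h2 <- run_once()
  expect_identical(h1$table, h2$table)
  expect_identical(h1$per_class_counts, h2$per_class_counts)
})

test_that("additions carry only oracle-approved truth under a perfect oracle", {
  cfg <- desk_config("cst_al", seed = 31)
  dir <- withr::local_tempdir()
  cfg$output_dir <- dir
  data <- desk_data(cfg)
  orc <- make_simulated_oracle(data$images, seed = 1)
  h <- run_experiment(cfg, data, orc)
  final <- read_pool_csv(file.path(dir, sprintf("round_%02d", cfg$rounds),
                                   "teacher_pool.csv"))
  truth <- vapply(data$images[final$records$image_id], `[[`,
                  character(1), "true_label")
  expect_true(all(final$records$label == truth))
  expect_true(file.exists(file.path(dir, "history.csv")))
})

test_that("the experiment aborts when the validation gate cannot be passed", {
  cfg <- desk_config("cst", seed = 41)
  cfg$validation_gate <- 0.999
  data <- desk_data(cfg)
  # scramble validation labels so gate accuracy hovers near chance
  set.seed(1)
  data$validation$labels <- sample(data$validation$labels)
  orc <- make_simulated_oracle(data$images, seed = 1)
  expect_error(run_experiment(cfg, data, orc), "validation gate")
})

test_that("an exhausted unlabeled pool stops the loop early with partial history", {
  cfg <- desk_config("al", seed = 51, rounds = 6L)
  data <- desk_data(cfg, unlabeled_per_class = 0L)  # nothing left to label
  orc <- make_simulated_oracle(data$images, seed = 1)
  expect_warning(h <- run_experiment(cfg, data, orc), "exhausted")
  expect_lt(nrow(h$table), 6)
  expect_true(all(diff(h$table$data_count) >= 0))
})

test_that("arm comparison joins histories and computes growth and shares", {
  arms <- c("cst_al", "cst", "al")
  histories <- lapply(arms, function(a) {
    cfg <- desk_config(a, seed = 61)
    data <- desk_data(cfg)
    orc <- make_simulated_oracle(data$images, seed = cfg$seed)
    run_experiment(cfg, data, orc)
  })
  dir <- withr::local_tempdir()
  rep <- compare_arms(histories, initial_per_class = 10, output_dir = dir)
  expect_equal(sort(unique(rep$history$table$arm)), sort(arms))
  expect_equal(nrow(rep$summary), 3)
  expect_length(rep$growth, 3)
  expect_true(file.exists(file.path(dir, "comparison.csv")))
  expect_true(file.exists(file.path(dir, "comparison.png")))
  expect_equal(sort(unique(rep$class_shares$arm)), sort(arms))

  single <- compare_arms(histories[1])
  expect_equal(nrow(single$summary), 1)

  short <- histories[[2]]
  short$table <- short$table[short$table$round < 3, ]
  expect_error(compare_arms(list(histories[[1]], short)), "different rounds")
})

test_that("margin sampling concentrates additions on the ambiguous class pair", {
  # meta_like (2.8) vs band_like (3.2) straddle the 3:1 criterion; margin
  # sampling should spend a larger share of its additions there than
  # confirmation of high-confidence images does
  cfgs <- list(al = desk_config("al", seed = 71, rounds = 4L),
               cst = desk_config("cst", seed = 71, rounds = 4L))
  shares <- lapply(cfgs, function(cfg) {
    data <- desk_data(cfg, unlabeled_per_class = 40L)
    orc <- make_simulated_oracle(data$images, seed = cfg$seed)
    h <- run_experiment(cfg, data, orc)
    pcc <- h$per_class_counts
    fin <- pcc[pcc$round == max(pcc$round), ]
    added <- fin$count - 10  # net of the seed images
    if (sum(added) == 0) return(NA_real_)
    sum(added[fin$class %in% c("meta_like", "band_like")]) / sum(added)
  })
  expect_gt(shares$al, shares$cst)
})

test_that("experiment configs round-trip through YAML", {
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("strategy: cst", "rounds: 4", "epochs_per_round: 7",
               "initial_per_class: 10", "seed: 3", "backend: moment",
               "input_size: 32"), path)
  cfg <- read_experiment_config(path)
  expect_equal(cfg$strategy, "cst")
  expect_equal(cfg$rounds, 4L)
  expect_equal(cfg$cst_threshold, 0.99)  # standalone confirmation default
  cfg2 <- read_experiment_config(path, strategy = "cst_al")
  expect_equal(cfg2$cst_threshold, 0.9)  # combined-strategy default
})
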