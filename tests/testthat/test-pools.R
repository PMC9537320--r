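ids_for <- function(cl, n) sprintf("%s_%03d", cl, seq_len(n))

test_that("teacher pool seeding yields per_class records per class at round 0", {
  by17 <- setNames(lapply(paste0("k", 1:17), ids_for, n = 30), paste0("k", 1:17))
  pool <- init_teacher_pool(by17, 25)
  expect_equal(pool_size(pool), 425)
  expect_true(all(pool$records$round_added == 0L))
  expect_true(all(table(pool$records$label) == 25))

  expect_equal(pool_size(init_teacher_pool(list(a = "x1"), 1)), 1)
  by6 <- setNames(lapply(letters[1:6], ids_for, n = 10), letters[1:6])
  expect_equal(pool_size(init_teacher_pool(by6, 10)), 60)
})

test_that("seeding fails naming the class that is short of images", {
  by2 <- list(plenty = ids_for("p", 30), scarce = ids_for("s", 3))
  expect_error(init_teacher_pool(by2, 10), "scarce")
})

test_that("unlabeled subsampling is uniform without replacement and seeded", {
  pool <- unlabeled_pool(ids_for("u", 600))
  s1 <- sample_unlabeled(pool, 50, seed = 7)
  s2 <- sample_unlabeled(pool, 50, seed = 7)
  expect_equal(pool_size(s1), 50)
  expect_false(anyDuplicated(s1$ids) > 0)
  expect_identical(s1$ids, s2$ids)
  expect_false(identical(s1$ids, sample_unlabeled(pool, 50, seed = 8)$ids))

  tiny <- unlabeled_pool(ids_for("t", 3))
  expect_setequal(sample_unlabeled(tiny, 5000, seed = 1)$ids, tiny$ids)
  expect_warning(empty <- sample_unlabeled(unlabeled_pool(character(0)), 5, seed = 1),
                 "empty")
  expect_equal(pool_size(empty), 0)
})

test_that("applying additions moves images between pools and keeps counts exact", {
  by17 <- setNames(lapply(paste0("k", 1:17), ids_for, n = 25), paste0("k", 1:17))
  teacher <- init_teacher_pool(by17, 25)
  unl <- unlabeled_pool(ids_for("u", 5000))
  adds <- data.frame(image_id = ids_for("u", 1269),
                     label = rep(paste0("k", 1:17), length.out = 1269))
  upd <- apply_additions(teacher, unl, adds, round = 2)
  expect_equal(pool_size(upd$teacher), 1694)
  expect_equal(pool_size(upd$unlabeled), 3731)
  expect_true(all(upd$teacher$records$round_added[426:1694] == 2L))

  noop <- apply_additions(teacher, unl, adds[0, ], round = 2)
  expect_identical(noop$teacher$records, teacher$records)

  taken <- data.frame(image_id = "k1_001", label = "k1")
  expect_error(apply_additions(teacher, unl, taken, round = 2), "double-add")
  dup <- data.frame(image_id = c("u_0001", "u_0001"), label = c("k1", "k2"))
  expect_error(apply_additions(teacher, unl, dup, round = 2), "duplicate")
})

make_class_pool <- function(n_old, n_new, newest = 5L, cap = 1000L) {
  recs <- data.frame(
    image_id = sprintf("im_%04d", seq_len(n_old + n_new)),
    label = "c",
    round_added = c(rep(1:3, length.out = n_old), rep(newest, n_new)))
  sslcyto:::new_teacher_pool(recs, cap)
}

test_that("balancing removes only old records, exactly down to the cap", {
  pool <- make_class_pool(950, 100)
  bal <- balance_classes(pool, cap = 1000, newest_round = 5, seed = 3)
  expect_equal(pool_size(bal), 1000)
  # brute-force check: all newest kept, removed ones all old
  newest_ids <- pool$records$image_id[pool$records$round_added == 5]
  expect_true(all(newest_ids %in% bal$records$image_id))
  removed <- setdiff(pool$records$image_id, bal$records$image_id)
  expect_length(removed, 50)
  expect_true(all(pool$records$round_added[match(removed, pool$records$image_id)] < 5))
})

test_that("balancing removes oldest rounds first", {
  recs <- data.frame(image_id = sprintf("im_%03d", 1:30), label = "c",
                     round_added = rep(c(1L, 2L, 3L), each = 10))
  pool <- sslcyto:::new_teacher_pool(recs, 15L)
  bal <- balance_classes(pool, cap = 15, newest_round = 3, seed = 1)
  kept <- table(factor(bal$records$round_added, levels = 1:3))
  expect_equal(unname(kept[["1"]]), 0)   # round 1 gone entirely
  expect_equal(unname(kept[["2"]]), 5)   # round 2 partially
  expect_equal(unname(kept[["3"]]), 10)  # newest untouched
})

test_that("balancing leaves small classes and all-newest overflow untouched", {
  under <- make_class_pool(300, 100)
  expect_identical(balance_classes(under, 1000, 5, seed = 1)$records,
                   under$records)
  all_new <- make_class_pool(0, 1200)
  bal <- balance_classes(all_new, 1000, 5, seed = 1)
  expect_equal(pool_size(bal), 1200)  # cap yields to the trained-once guarantee
})

test_that("balancing is idempotent", {
  pool <- make_class_pool(950, 100)
  once <- balance_classes(pool, 1000, 5, seed = 42)
  twice <- balance_classes(once, 1000, 5, seed = 42)
  expect_identical(once$records, twice$records)
})

test_that("teacher and unlabeled ids stay disjoint over random operation sequences", {
  set.seed(14)
  for (rep in 1:5) {
    classes <- letters[1:4]
    by_cl <- setNames(lapply(classes, ids_for, n = 5), classes)
    teacher <- init_teacher_pool(by_cl, 5, per_class_cap = 12L)
    unl <- unlabeled_pool(ids_for("u", 200))
    sizes <- pool_size(teacher)
    for (round in 2:6) {
      sub <- sample_unlabeled(unl, 30, seed = round * rep)
      take <- sub$ids[seq_len(sample(0:20, 1))]
      adds <- data.frame(image_id = take,
                         label = sample(classes, length(take), replace = TRUE))
      upd <- apply_additions(teacher, unl, adds, round = round)
      teacher <- upd$teacher; unl <- upd$unlabeled
      expect_length(intersect(teacher$records$image_id, unl$ids), 0)
      sizes <- c(sizes, pool_size(teacher))
      balanced <- balance_classes(teacher, 12, newest_round = round, seed = round)
      expect_true(all(teacher$records$image_id[teacher$records$round_added == round]
                      %in% balanced$records$image_id))
    }
    expect_true(all(diff(sizes) >= 0))  # pool growth is monotone
  }
})
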