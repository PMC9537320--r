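pm <- function(m, classes = paste0("c", seq_len(ncol(m)))) {
  colnames(m) <- classes
  prediction_matrix(sprintf("im%02d", seq_len(nrow(m))), m)
}

test_that("prediction matrix rejects malformed probability rows", {
  bad <- matrix(c(0.6, 0.3, 0.5, 0.5), 2, byrow = TRUE)
  colnames(bad) <- c("a", "b")
  expect_error(prediction_matrix(c("x", "y"), bad), "row 1")
  expect_silent(pm(matrix(c(0.5, 0.5), 1)))
})

test_that("confidence selection is inclusive at the threshold", {
  p <- pm(rbind(c(0.995, 0.003, 0.002),
                c(0.989, 0.011, 0.000),
                c(0.990, 0.007, 0.003)))
  sel <- cst_candidates(p, 0.99)
  expect_setequal(sel$image_id, c("im01", "im03"))  # 0.99 itself is selected
  expect_equal(sel$pseudo_label[sel$image_id == "im01"], "c1")
})

test_that("confidence selection matches a brute-force row scan", {
  p <- pm(rbind(c(0.99, 0.005, 0.005),
                c(0.50, 0.30, 0.20),
                c(0.999, 0.0005, 0.0005),
                c(0.90, 0.05, 0.05)))
  sel <- cst_candidates(p, 0.99)
  expect_identical(sel$image_id, c("im01", "im03"))
})

test_that("margin selection is strict at the threshold", {
  p <- pm(rbind(c(0.55, 0.45), c(0.60, 0.40)))
  sel <- margin_candidates(p, 0.2)
  expect_identical(sel$image_id, "im01")   # margin 0.10 in, exactly 0.20 out
  expect_equal(sel$margin, 0.10, tolerance = 1e-12)
})

test_that("margin selection matches brute-force margins and needs >= 2 classes", {
  margins <- c(0.05, 0.8, 0.19, 0.21, 0.2)
  rows <- t(vapply(margins, function(m) {
    p1 <- (1 + m) / 2
    c(p1, p1 - m)
  }, numeric(2)))
  sel <- margin_candidates(pm(rows), 0.2)
  expect_identical(sel$image_id, c("im01", "im03"))
  one <- prediction_matrix("x", matrix(1, 1, 1, dimnames = list(NULL, "only")))
  expect_error(margin_candidates(one, 0.2), "two classes")
})

test_that("argmax ties break toward the lowest class index", {
  p <- pm(matrix(c(0.5, 0.5, 0, 0.25, 0.25, 0.5), 2, byrow = TRUE))
  tab <- sslcyto:::candidate_table(p)
  expect_equal(tab$pseudo_label[1], "c1")
  expect_equal(tab$margin[1], 0)
})

test_that("confirmation keeps, corrects or drops candidates in input order", {
  ids <- paste0("q", 1:4)
  truths <- c("myelocyte", "metamyelocyte", "myelocyte", "band")
  orc <- oracle_for(ids, truths)
  cands <- data.frame(image_id = ids,
                      pseudo_label = c("myelocyte", "myelocyte", "myelocyte", "band"),
                      top_prob = 0.99, margin = 0.9)
  adds <- confirm_candidates(cands, orc)
  expect_identical(adds$image_id, ids)  # order preserved, none rejected
  # wrong pseudo label was corrected to the truth
  expect_equal(adds$label[2], "metamyelocyte")
  expect_equal(adds$label[c(1, 3, 4)], truths[c(1, 3, 4)])

  rejecting <- oracle_for(ids, truths, reject_rate = 1)
  expect_equal(nrow(confirm_candidates(cands, rejecting)), 0)
})

test_that("an oracle failure is treated as a rejection with a warning", {
  orc <- oracle_for("known", "myelocyte")
  cands <- data.frame(image_id = c("known", "unknown"),
                      pseudo_label = "myelocyte", top_prob = 0.99, margin = 0.9)
  expect_warning(adds <- confirm_candidates(cands, orc), "unknown")
  expect_identical(adds$image_id, "known")
})

test_that("labeling queries return the oracle's labels and honor skips", {
  ids <- paste0("a", 1:10)
  truths <- rep(c("meta_like", "band_like"), 5)
  cands <- data.frame(image_id = ids, pseudo_label = "meta_like",
                      top_prob = 0.6, margin = 0.1)
  perfect <- oracle_for(ids, truths)
  adds <- label_queries(cands, perfect)
  expect_identical(adds$label, truths)  # perfect oracle returns hidden truth
  skipall <- oracle_for(ids, truths, reject_rate = 1)
  expect_equal(nrow(label_queries(cands, skipall)), 0)
})

test_that("selection is a pure function of matrix and thresholds", {
  set.seed(31)
  p <- pm(random_prob_matrix(200, 6))
  expect_identical(cst_candidates(p, 0.9), cst_candidates(p, 0.9))
  expect_identical(margin_candidates(p, 0.2), margin_candidates(p, 0.2))
})

test_that("selection is monotone in its thresholds", {
  set.seed(32)
  p <- pm(random_prob_matrix(300, 5))
  for (th in c(0.99, 0.95, 0.9, 0.8, 0.6)) {
    lower <- cst_candidates(p, max(th - 0.05, 0.51))$image_id
    expect_true(all(cst_candidates(p, th)$image_id %in% lower))
  }
  for (mt in c(0.05, 0.1, 0.2, 0.4)) {
    wider <- margin_candidates(p, min(mt + 0.1, 0.99))$image_id
    expect_true(all(margin_candidates(p, mt)$image_id %in% wider))
  }
})

test_that("combined selection equals the union of both routes with disjoint inputs", {
  set.seed(33)
  probs <- random_prob_matrix(100, 17)
  ids <- sprintf("d%03d", 1:100)
  classes <- colnames(probs)
  p <- prediction_matrix(ids, probs)
  truths <- classes[max.col(probs)]
  both <- combined_selection(p, 0.9, 0.2, oracle_for(ids, truths))
  cst_only <- confirm_candidates(cst_candidates(p, 0.9), oracle_for(ids, truths))
  al_only <- label_queries(margin_candidates(p, 0.2), oracle_for(ids, truths))
  expect_equal(nrow(both), nrow(cst_only) + nrow(al_only))
  expect_length(intersect(cst_candidates(p, 0.9)$image_id,
                          margin_candidates(p, 0.2)$image_id), 0)
})

test_that("threshold combinations that break disjointness fall back with a warning", {
  # margin 0.3 > 2*0.6-1 = 0.2: a row like (0.62, 0.38) matches both rules
  p <- pm(rbind(c(0.62, 0.38), c(0.95, 0.05)))
  orc <- oracle_for(c("im01", "im02"), c("c1", "c1"))
  expect_warning(adds <- combined_selection(p, 0.6, 0.3, orc), "disjoint")
  expect_equal(sum(adds$image_id == "im01"), 1)  # claimed once, by confirmation
})
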