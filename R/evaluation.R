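#' Confusion matrix over evaluation classes
#'
#' Tallies truth against prediction after mapping both through the
#' taxonomy's merge map, so training classes that share an evaluation class
#' (bare nuclei and artifacts in the bone-marrow configuration) are counted
#' as one. Rows are truth, columns are prediction.
#'
#' @param truths,preds equal-length character vectors of training-class
#'   labels.
#' @param taxonomy a [label_taxonomy()].
#' @return an E x E integer matrix of class `confusion_matrix`, E the number
#'   of evaluation classes.
#' @export
confusion_matrix <- function(truths, preds, taxonomy) {
  stopifnot(length(truths) == length(preds))
  t_m <- factor(merge_labels(truths, taxonomy), levels = taxonomy$eval_classes)
  p_m <- factor(merge_labels(preds, taxonomy), levels = taxonomy$eval_classes)
  cm <- table(truth = t_m, prediction = p_m)
  structure(unclass(cm), class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat("confusion_matrix (", nrow(x), "evaluation classes,", sum(x), "images )\n")
  print(unclass(x))
  invisible(x)
}

#' Per-class recall and precision, macro averages, overall accuracy
#'
#' Recall is the diagonal over the row sum, precision the diagonal over the
#' column sum, accuracy the trace over the grand total. Macro averages are
#' unweighted means over classes; classes with a zero denominator are
#' reported as `NaN` and excluded from the macro average with a warning.
#'
#' @param cm a [confusion_matrix()].
#' @return list with `per_class` (data.frame: class, recall, precision),
#'   `macro_recall`, `macro_precision`, `accuracy`.
#' @export
per_class_metrics <- function(cm) {
  stopifnot(inherits(cm, "confusion_matrix"))
  total <- sum(cm)
  if (total == 0) stop("confusion matrix is empty")
  d <- diag(cm)
  rs <- rowSums(cm); cs <- colSums(cm)
  recall <- ifelse(rs > 0, d / rs, NaN)
  precision <- ifelse(cs > 0, d / cs, NaN)
  if (anyNA(c(recall, precision)))
    warning("class(es) with zero row or column sum excluded from macro averages")
  list(per_class = data.frame(class = rownames(cm), recall = recall,
                              precision = precision, row.names = NULL),
       macro_recall = mean(recall, na.rm = TRUE),
       macro_precision = mean(precision, na.rm = TRUE),
       accuracy = sum(d) / total)
}

#' Per-round experiment history
#'
#' One row per (arm, round): the test accuracy of the model trained at that
#' round and the cumulative teacher-pool size (DATA_Count) it was trained
#' on. Optionally carries per-class cumulative added counts.
#'
#' @param df data.frame with columns `arm`, `round`, `accuracy`,
#'   `data_count`.
#' @param per_class_counts optional data.frame of per-class cumulative
#'   counts with columns `arm`, `round`, `class`, `count`.
#' @param n_classes number of training classes behind the counts.
#' @return an object of class `round_history`.
#' @export
round_history <- function(df, per_class_counts = NULL, n_classes = NA_integer_) {
  stopifnot(all(c("arm", "round", "accuracy", "data_count") %in% names(df)))
  if (any(df$accuracy < 0 | df$accuracy > 1))
    stop("accuracy must lie in [0, 1]")
  for (a in unique(df$arm)) {
    sub <- df[df$arm == a, ]
    sub <- sub[order(sub$round), ]
    if (any(diff(sub$data_count) < 0))
      stop("data_count must be non-decreasing within arm '", a, "'")
  }
  rownames(df) <- NULL
  structure(list(table = df, per_class_counts = per_class_counts,
                 n_classes = as.integer(n_classes)),
            class = "round_history")
}

#' @export
print.round_history <- function(x, ...) {
  arms <- unique(x$table$arm)
  cat("round_history:", paste(arms, collapse = ", "), "|",
      max(x$table$round), "rounds\n")
  invisible(x)
}

#' Round-over-round growth statistics of cumulative teacher counts
#'
#' For a cumulative count series A (per class or in total), computes for
#' every round n >= 2 the growth ratio `A[n] / A[n-1]`, the difference
#' `A[n] - A[n-1]`, and the per-round increase expressed relative to the
#' initial per-class seed size (`(A[n] - A[n-1]) / initial_per_class`,
#' divisor 25 in the reference configuration). A zero previous count gives
#' a missing ratio.
#'
#' @param counts numeric vector of cumulative counts by round, or a matrix
#'   with one row per class and one column per round.
#' @param initial_per_class divisor of the relative increase rate (25).
#' @return list of matrices (or vectors, matching the input shape) `ratio`,
#'   `difference`, `rate_vs_initial`, each with one column per round
#'   transition, plus `mean` and `sem` of each statistic over all entries.
#' @export
growth_statistics <- function(counts, initial_per_class = 25) {
  vec_in <- is.null(dim(counts))
  m <- if (vec_in) matrix(counts, nrow = 1) else as.matrix(counts)
  if (ncol(m) < 2L) stop("need counts for at least two rounds")
  if (any(apply(m, 1, function(r) any(diff(r) < 0))))
    stop("cumulative counts must be non-decreasing")
  prev <- m[, -ncol(m), drop = FALSE]
  cur <- m[, -1L, drop = FALSE]
  ratio <- ifelse(prev > 0, cur / prev, NA_real_)
  difference <- cur - prev
  rate <- difference / initial_per_class
  sem <- function(x) stats::sd(x, na.rm = TRUE) / sqrt(sum(!is.na(x)))
  unshape <- function(x) if (vec_in) drop(x) else x
  list(ratio = unshape(ratio), difference = unshape(difference),
       rate_vs_initial = unshape(rate),
       mean = c(ratio = mean(ratio, na.rm = TRUE),
                difference = mean(difference),
                rate_vs_initial = mean(rate)),
       sem = c(ratio = sem(ratio), difference = sem(difference),
               rate_vs_initial = sem(rate)))
}

#' Summary statistics of a multi-arm round history
#'
#' Per arm: mean, standard error (sample SD over sqrt(n)) and best test
#' accuracy over the rounds; the final cumulative teacher count; and the
#' per-class mean of the final count (final count divided by the number of
#' training classes, seed images included).
#'
#' @param history a [round_history()].
#' @param n_classes number of training classes (defaults to the history's).
#' @param expected_rounds if given, every arm must cover rounds
#'   `1:expected_rounds` (missing rounds are an error).
#' @return data.frame with one row per arm: `arm`, `n_rounds`,
#'   `mean_accuracy`, `sem_accuracy`, `best_accuracy`, `final_count`,
#'   `per_class_mean_final`.
#' @export
summarize_history <- function(history, n_classes = history$n_classes,
                              expected_rounds = NULL) {
  stopifnot(inherits(history, "round_history"))
  df <- history$table
  out <- lapply(split(df, df$arm), function(sub) {
    sub <- sub[order(sub$round), ]
    if (!is.null(expected_rounds)) {
      missing <- setdiff(seq_len(expected_rounds), sub$round)
      if (length(missing))
        stop("arm '", sub$arm[1], "' is missing round(s): ",
             paste(missing, collapse = ", "))
    }
    n <- nrow(sub)
    data.frame(arm = sub$arm[1], n_rounds = n,
               mean_accuracy = mean(sub$accuracy),
               sem_accuracy = stats::sd(sub$accuracy) / sqrt(n),
               best_accuracy = max(sub$accuracy),
               final_count = sub$data_count[n],
               per_class_mean_final = sub$data_count[n] / n_classes)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Write a round history in the wide reference-table layout
#'
#' Columns `Accuracy_<arm>` and `DATA_Count_<arm>` per arm, one row per
#' round — the layout of the published round-history table.
#'
#' @param history a [round_history()].
#' @param path CSV path.
#' @return `path`, invisibly.
#' @export
write_history_csv <- function(history, path) {
  stopifnot(inherits(history, "round_history"))
  df <- history$table
  arms <- unique(df$arm)
  rounds <- sort(unique(df$round))
  out <- data.frame(round = rounds)
  for (a in arms) {
    sub <- df[df$arm == a, ]
    sub <- sub[match(rounds, sub$round), ]
    out[[paste0("Accuracy_", toupper(a))]] <- sub$accuracy
    out[[paste0("DATA_Count_", toupper(a))]] <- sub$data_count
  }
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}
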