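#' Prediction matrix
#'
#' Per-image class-probability vectors from the current classifier, the
#' single artifact both selection strategies read. Rows must be proper
#' probability vectors (non-negative, summing to 1 within 1e-6).
#'
#' @param image_ids character vector of length N.
#' @param probs N x C numeric matrix; column names are the training classes.
#' @return An object of class `prediction_matrix`.
#' @export
prediction_matrix <- function(image_ids, probs) {
  probs <- as.matrix(probs)
  if (length(image_ids) != nrow(probs))
    stop("image_ids and probs row count differ")
  if (is.null(colnames(probs)))
    stop("probs must carry class names as column names")
  if (nrow(probs) > 0) {
    if (any(probs < -1e-9) || any(probs > 1 + 1e-9))
      stop("probabilities must lie in [0, 1]")
    sums <- rowSums(probs)
    bad <- which(abs(sums - 1) > 1e-6)
    if (length(bad))
      stop("probability row(s) do not sum to 1: row ",
           paste(utils::head(bad, 5L), collapse = ", "))
  }
  structure(list(image_ids = as.character(image_ids), probs = probs),
            class = "prediction_matrix")
}

#' @export
print.prediction_matrix <- function(x, ...) {
  cat(sprintf("prediction_matrix: %d images x %d classes\n",
              nrow(x$probs), ncol(x$probs)))
  invisible(x)
}

# top class, top probability and top-two margin per row;
# argmax ties broken by the lowest class index
candidate_table <- function(preds) {
  p <- preds$probs
  n <- nrow(p)
  if (n == 0L)
    return(data.frame(image_id = character(0), pseudo_label = character(0),
                      top_prob = numeric(0), margin = numeric(0)))
  top_idx <- max.col(p, ties.method = "first")
  top_prob <- p[cbind(seq_len(n), top_idx)]
  second <- vapply(seq_len(n), function(i) {
    r <- p[i, -top_idx[i]]
    if (length(r)) max(r) else NA_real_
  }, numeric(1))
  data.frame(image_id = preds$image_ids,
             pseudo_label = colnames(p)[top_idx],
             top_prob = top_prob,
             margin = top_prob - second,
             stringsAsFactors = FALSE)
}

#' Confirmed self-training candidates: high-confidence pseudo labels
#'
#' Selects every image whose top predicted probability reaches `threshold`
#' (inclusive: a top probability exactly at the threshold is selected). The
#' argmax class becomes the candidate's pseudo label, to be verified by an
#' examiner before it may enter the teacher pool.
#'
#' @param preds a [prediction_matrix()].
#' @param threshold confidence threshold in `(0.5, 1]`; the standalone
#'   reference configuration uses 0.99, the combined strategy 0.9.
#' @return data.frame of candidates with columns `image_id`, `pseudo_label`,
#'   `top_prob`, `margin`, in input row order.
#' @export
cst_candidates <- function(preds, threshold = 0.99) {
  stopifnot(inherits(preds, "prediction_matrix"),
            threshold > 0.5, threshold <= 1)
  tab <- candidate_table(preds)
  # tolerance keeps the inclusive boundary exact for probabilities that are
  # decimal-printed (e.g. 0.99) but not binary-representable
  tab[tab$top_prob >= threshold - 1e-9, , drop = FALSE]
}

#' Margin-sampling candidates for active learning
#'
#' Selects every image whose margin — the gap between the highest and
#' second-highest class probability — is strictly below `margin_threshold`.
#' These are the images the classifier is least decided about; an examiner
#' labels them from scratch.
#'
#' @param preds a [prediction_matrix()] with at least two classes.
#' @param margin_threshold margin cut-off in `(0, 1)`; reference value 0.2.
#' @return data.frame of candidates (same columns as [cst_candidates()]).
#' @export
margin_candidates <- function(preds, margin_threshold = 0.2) {
  stopifnot(inherits(preds, "prediction_matrix"),
            margin_threshold > 0, margin_threshold < 1)
  if (ncol(preds$probs) < 2L)
    stop("margin sampling needs at least two classes")
  tab <- candidate_table(preds)
  # strict boundary, robust to float rounding: a margin within 1e-9 of the
  # threshold counts as equal and is excluded
  tab[tab$margin < margin_threshold - 1e-9, , drop = FALSE]
}

#' Examiner confirmation of pseudo-labeled candidates
#'
#' Each candidate's pseudo label is put to the oracle, which may confirm it,
#' re-attach the correct label, or reject the image as too hard to judge
#' (rejected images are not added and stay unlabeled). An oracle failure on
#' an id is treated as a rejection and logged.
#'
#' @param candidates data.frame from [cst_candidates()].
#' @param oracle an oracle handle; see [make_simulated_oracle()] for the
#'   query contract.
#' @return data.frame of additions with columns `image_id`, `label`, in
#'   candidate order.
#' @export
confirm_candidates <- function(candidates, oracle) {
  out_id <- character(0); out_lab <- character(0)
  for (i in seq_len(nrow(candidates))) {
    resp <- tryCatch(
      oracle_query(oracle, candidates$image_id[i],
                   pseudo_label = candidates$pseudo_label[i], type = "cst"),
      error = function(e) {
        warning("oracle failed on '", candidates$image_id[i],
                "'; treating as reject: ", conditionMessage(e))
        list(verdict = "reject")
      })
    if (resp$verdict == "confirm") {
      out_id <- c(out_id, candidates$image_id[i])
      out_lab <- c(out_lab, candidates$pseudo_label[i])
    } else if (resp$verdict == "relabel") {
      out_id <- c(out_id, candidates$image_id[i])
      out_lab <- c(out_lab, resp$label)
    }
  }
  data.frame(image_id = out_id, label = out_lab, stringsAsFactors = FALSE)
}

#' Examiner labeling of margin-sampled candidates
#'
#' The oracle supplies a label de novo for each queried image, or skips it
#' when labeling is too difficult (skipped images are not added).
#'
#' @inheritParams confirm_candidates
#' @param candidates data.frame from [margin_candidates()].
#' @return data.frame of additions with columns `image_id`, `label`.
#' @export
label_queries <- function(candidates, oracle) {
  out_id <- character(0); out_lab <- character(0)
  for (i in seq_len(nrow(candidates))) {
    resp <- tryCatch(
      oracle_query(oracle, candidates$image_id[i], type = "al"),
      error = function(e) {
        warning("oracle failed on '", candidates$image_id[i],
                "'; treating as skip: ", conditionMessage(e))
        list(verdict = "skip")
      })
    if (resp$verdict == "label") {
      out_id <- c(out_id, candidates$image_id[i])
      out_lab <- c(out_lab, resp$label)
    }
  }
  data.frame(image_id = out_id, label = out_lab, stringsAsFactors = FALSE)
}

#' Combined selection: confirmed self-training and active learning in parallel
#'
#' Runs both strategies on the same prediction matrix: high-confidence
#' pseudo labels go to examiner confirmation, low-margin images to examiner
#' labeling, and the two addition sets are pooled. Whenever
#' `2 * cst_threshold - 1 >= margin_threshold` the two candidate sets are
#' provably disjoint (a top probability of at least theta forces a margin of
#' at least 2*theta - 1), which holds at the reference settings theta = 0.9,
#' m = 0.2. If the configured thresholds break that guarantee, images caught
#' by both rules are claimed by the confirmation route and a warning is
#' emitted.
#'
#' @inheritParams cst_candidates
#' @param cst_threshold confidence threshold for the confirmation route
#'   (default 0.9 in the combined strategy).
#' @param margin_threshold margin cut-off for the labeling route (default 0.2).
#' @param oracle oracle handle answering both query types.
#' @return data.frame of additions with columns `image_id`, `label`.
#' @export
combined_selection <- function(preds, cst_threshold = 0.9,
                               margin_threshold = 0.2, oracle) {
  cst <- cst_candidates(preds, cst_threshold)
  al <- margin_candidates(preds, margin_threshold)
  if (2 * cst_threshold - 1 < margin_threshold) {
    overlap <- intersect(cst$image_id, al$image_id)
    if (length(overlap)) {
      warning("thresholds do not guarantee disjoint candidate sets; ",
              length(overlap), " image(s) claimed by the confirmation route")
      al <- al[!al$image_id %in% overlap, , drop = FALSE]
    }
  }
  rbind(confirm_candidates(cst, oracle), label_queries(al, oracle))
}

#' Read / write a prediction matrix as CSV
#'
#' The on-disk form mirrors the per-round "prediction result file": one row
#' per image, an `image_id` column and one probability column per class.
#'
#' @param preds a [prediction_matrix()].
#' @param path CSV file path.
#' @return `read_prediction_csv` returns a [prediction_matrix()];
#'   `write_prediction_csv` returns `path` invisibly.
#' @export
write_prediction_csv <- function(preds, path) {
  stopifnot(inherits(preds, "prediction_matrix"))
  df <- data.frame(image_id = preds$image_ids, preds$probs,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_prediction_csv
#' @export
read_prediction_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  prediction_matrix(df$image_id,
                    as.matrix(df[, setdiff(names(df), "image_id"), drop = FALSE]))
}
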