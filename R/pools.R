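#' Teacher and unlabeled pools
#'
#' The teacher pool is the labeled training set; each record remembers the
#' round at which its image was added (round 0 is the initial seed data).
#' The unlabeled pool is the complement: image ids with no label yet. The
#' two id sets are disjoint at all times, and an image moves from one pool
#' to the other exactly once, when an examiner-approved label is attached.
#'
#' @name pools
NULL

new_teacher_pool <- function(records, per_class_cap = 1000L) {
  stopifnot(is.data.frame(records),
            all(c("image_id", "label", "round_added") %in% names(records)))
  if (anyDuplicated(records$image_id))
    stop("duplicate image ids in teacher pool")
  records$image_id <- as.character(records$image_id)
  records$label <- as.character(records$label)
  records$round_added <- as.integer(records$round_added)
  rownames(records) <- NULL
  structure(list(records = records, per_class_cap = as.integer(per_class_cap)),
            class = "teacher_pool")
}

#' @export
print.teacher_pool <- function(x, ...) {
  cat(sprintf("teacher_pool: %d records, %d classes, per-class cap %d\n",
              nrow(x$records), length(unique(x$records$label)), x$per_class_cap))
  invisible(x)
}

#' Number of records in a pool
#' @param pool a `teacher_pool` or `unlabeled_pool`.
#' @return integer count.
#' @export
pool_size <- function(pool) {
  if (inherits(pool, "teacher_pool")) nrow(pool$records)
  else if (inherits(pool, "unlabeled_pool")) length(pool$ids)
  else stop("not a pool")
}

#' Create an unlabeled pool from image ids
#' @param ids character vector of image ids (no observed label).
#' @return An object of class `unlabeled_pool`.
#' @export
unlabeled_pool <- function(ids) {
  ids <- as.character(ids)
  if (anyDuplicated(ids)) stop("duplicate image ids in unlabeled pool")
  structure(list(ids = ids), class = "unlabeled_pool")
}

#' @export
print.unlabeled_pool <- function(x, ...) {
  cat(sprintf("unlabeled_pool: %d images\n", length(x$ids)))
  invisible(x)
}

#' Initialize the teacher pool with a fixed number of seed images per class
#'
#' Seeds the labeled pool with `per_class` images from every class (the
#' reference configuration uses 25 images in each of 17 classes, a 425-image
#' seed). All seed records carry `round_added = 0`.
#'
#' @param images_by_class named list mapping class name to a character vector
#'   of image ids available for that class.
#' @param per_class number of seed images to take per class (taken in the
#'   order given; shuffle beforehand if a random seed set is wanted).
#' @param per_class_cap balancing cap carried by the pool (default 1000).
#' @return a `teacher_pool` with `per_class * length(images_by_class)` records.
#' @export
init_teacher_pool <- function(images_by_class, per_class, per_class_cap = 1000L) {
  stopifnot(is.list(images_by_class), !is.null(names(images_by_class)),
            per_class >= 1L)
  n_avail <- vapply(images_by_class, length, integer(1))
  short <- names(images_by_class)[n_avail < per_class]
  if (length(short))
    stop("not enough images to seed class(es): ", paste(short, collapse = ", "),
         " (need ", per_class, ")")
  recs <- do.call(rbind, lapply(names(images_by_class), function(cl) {
    data.frame(image_id = images_by_class[[cl]][seq_len(per_class)],
               label = cl, round_added = 0L, stringsAsFactors = FALSE)
  }))
  new_teacher_pool(recs, per_class_cap)
}

#' Randomly subsample the unlabeled pool
#'
#' Each round works on a random subsample of the unlabeled pool (5000 images
#' in the reference configuration) rather than the whole pool, keeping the
#' number of selection candidates manageable. Sampling is uniform without
#' replacement and reproducible under `seed`.
#'
#' @param pool an `unlabeled_pool`.
#' @param n requested sample size; if the pool is smaller the whole pool is
#'   returned.
#' @param seed integer seed for the draw.
#' @return an `unlabeled_pool` with `min(n, pool size)` ids.
#' @export
sample_unlabeled <- function(pool, n, seed) {
  stopifnot(inherits(pool, "unlabeled_pool"), n >= 1L)
  if (length(pool$ids) == 0L) {
    warning("unlabeled pool is empty; returning empty subset")
    return(unlabeled_pool(character(0)))
  }
  k <- min(as.integer(n), length(pool$ids))
  ids <- with_seed(seed, sample(pool$ids, k, replace = FALSE))
  unlabeled_pool(ids)
}

#' Move newly labeled images from the unlabeled pool into the teacher pool
#'
#' Applies one round's examiner-approved additions: each `(image_id, label)`
#' pair is appended to the teacher pool with `round_added = round` and
#' removed from the unlabeled pool, preserving disjointness. Attempting to
#' add an id that is not currently unlabeled (e.g. already a teacher record)
#' is an error.
#'
#' @param teacher a `teacher_pool`.
#' @param unlabeled an `unlabeled_pool` containing every addition id.
#' @param additions data.frame with columns `image_id` and `label` (may have
#'   zero rows).
#' @param round integer round index recorded on the new records.
#' @return list with elements `teacher` and `unlabeled`, the updated pools.
#' @export
apply_additions <- function(teacher, unlabeled, additions, round) {
  stopifnot(inherits(teacher, "teacher_pool"), inherits(unlabeled, "unlabeled_pool"))
  if (is.null(additions) || nrow(additions) == 0L)
    return(list(teacher = teacher, unlabeled = unlabeled))
  stopifnot(all(c("image_id", "label") %in% names(additions)))
  ids <- as.character(additions$image_id)
  if (anyDuplicated(ids))
    stop("duplicate image ids within additions")
  missing <- setdiff(ids, unlabeled$ids)
  if (length(missing))
    stop("addition ids not in the unlabeled pool (double-add guard): ",
         paste(utils::head(missing, 5L), collapse = ", "))
  new <- data.frame(image_id = ids, label = as.character(additions$label),
                    round_added = as.integer(round), stringsAsFactors = FALSE)
  teacher2 <- new_teacher_pool(rbind(teacher$records, new), teacher$per_class_cap)
  unlabeled2 <- unlabeled_pool(setdiff(unlabeled$ids, ids))
  list(teacher = teacher2, unlabeled = unlabeled2)
}

#' Cap per-class teacher counts while protecting the newest additions
#'
#' Before each training round the pool is rebalanced so no class greatly
#' outweighs the others: a class holding more than `cap` records sheds
#' records added in earlier rounds until it is back at the cap. Records from
#' `newest_round` are never deleted — every newly added image is guaranteed
#' to be trained on at least once — so a class whose newest additions alone
#' exceed the cap is left above it. Deletions take the oldest rounds first;
#' ties within a round are broken uniformly at random under `seed`.
#'
#' @param teacher a `teacher_pool`.
#' @param cap per-class ceiling (defaults to the pool's `per_class_cap`).
#' @param newest_round round index whose records are protected.
#' @param seed integer seed for random tie-breaking.
#' @return a rebalanced `teacher_pool`.
#' @export
balance_classes <- function(teacher, cap = teacher$per_class_cap, newest_round, seed) {
  stopifnot(inherits(teacher, "teacher_pool"), cap >= 1L)
  recs <- teacher$records
  keep <- rep(TRUE, nrow(recs))
  with_seed(seed, {
    for (cl in unique(recs$label)) {
      idx <- which(recs$label == cl)
      if (length(idx) <= cap) next
      old <- idx[recs$round_added[idx] < newest_round]
      n_newest <- length(idx) - length(old)
      n_remove <- min(length(old), length(idx) - cap)
      if (n_remove == 0L) next
      # oldest rounds go first; random order within a round
      ord <- old[order(recs$round_added[old], stats::runif(length(old)))]
      keep[ord[seq_len(n_remove)]] <- FALSE
    }
  })
  new_teacher_pool(recs[keep, , drop = FALSE], teacher$per_class_cap)
}

#' Per-class record counts of a teacher pool
#' @param teacher a `teacher_pool`.
#' @return named integer vector of counts by class.
#' @export
class_counts <- function(teacher) {
  stopifnot(inherits(teacher, "teacher_pool"))
  tab <- table(teacher$records$label)
  stats::setNames(as.integer(tab), names(tab))
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`,
# restoring the caller's stream afterwards.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}
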