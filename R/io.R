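#' Write and read single-cell image datasets (PNG + CSV manifest)
#'
#' A dataset on disk is a directory of 8-bit RGB PNGs plus a manifest CSV
#' with columns `image_id,path,label` (`path` relative to the manifest, a
#' header row, comma separators, UTF-8). An empty `label` marks an
#' unlabeled image; hidden synthetic ground truth is never written.
#'
#' @param images list of [cell_image()]s.
#' @param dir output directory (created if needed).
#' @param manifest manifest file name within `dir`.
#' @return `write_dataset` returns the manifest path invisibly;
#'   `read_dataset` returns a named list of `cell_image`s (names = ids).
#' @export
write_dataset <- function(images, dir, manifest = "manifest.csv") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- lapply(images, function(img) {
    fn <- paste0(img$id, ".png")
    png::writePNG(img$pixels, file.path(dir, fn))
    data.frame(image_id = img$id, path = fn,
               label = if (is.null(img$observed_label)) "" else img$observed_label,
               stringsAsFactors = FALSE)
  })
  mf <- file.path(dir, manifest)
  utils::write.csv(do.call(rbind, rows), mf, row.names = FALSE)
  invisible(mf)
}

#' @rdname write_dataset
#' @param manifest_path path to a manifest CSV.
#' @export
read_dataset <- function(manifest_path) {
  df <- utils::read.csv(manifest_path, stringsAsFactors = FALSE,
                        colClasses = "character")
  stopifnot(all(c("image_id", "path", "label") %in% names(df)))
  base <- dirname(manifest_path)
  imgs <- lapply(seq_len(nrow(df)), function(i) {
    px <- png::readPNG(file.path(base, df$path[i]))
    if (length(dim(px)) == 2L) px <- array(rep(px, 3L), c(dim(px), 3L))
    if (dim(px)[3] == 4L) px <- px[, , 1:3, drop = FALSE]
    lab <- df$label[i]
    cell_image(df$image_id[i], px,
               observed_label = if (nzchar(lab)) lab else NULL)
  })
  stats::setNames(imgs, df$image_id)
}

#' Split a named image list into teacher candidates and unlabeled ids
#'
#' Images with an observed label become teacher candidates grouped by
#' class; the rest form the unlabeled pool.
#'
#' @param images named list of [cell_image()]s.
#' @return list with `images_by_class` (named list of id vectors) and
#'   `unlabeled` (an [unlabeled_pool()]).
#' @export
split_by_label <- function(images) {
  labs <- vapply(images, function(i)
    if (is.null(i$observed_label)) "" else i$observed_label, character(1))
  ids <- vapply(images, `[[`, character(1), "id")
  by_class <- split(ids[nzchar(labs)], labs[nzchar(labs)])
  list(images_by_class = by_class,
       unlabeled = unlabeled_pool(ids[!nzchar(labs)]))
}

#' Serialize a teacher pool snapshot to CSV
#'
#' @param teacher a `teacher_pool`.
#' @param path CSV path (columns `image_id,label,round_added`).
#' @return `path`, invisibly.
#' @export
write_pool_csv <- function(teacher, path) {
  stopifnot(inherits(teacher, "teacher_pool"))
  utils::write.csv(teacher$records, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_pool_csv
#' @param per_class_cap cap restored onto the pool.
#' @export
read_pool_csv <- function(path, per_class_cap = 1000L) {
  new_teacher_pool(utils::read.csv(path, stringsAsFactors = FALSE),
                   per_class_cap)
}
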