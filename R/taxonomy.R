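#' Label taxonomy with a training-to-evaluation merge map
#'
#' The classifier is trained over a fine-grained set of classes, but some
#' pairs that cannot be told apart reliably by eye (classically, bare nuclei
#' and staining artifacts) are merged into a single class when scoring.
#' A taxonomy records the ordered training classes together with a map from
#' each training class to its evaluation class.
#'
#' @param training_classes character vector of unique training class names,
#'   in the order used for probability columns.
#' @param eval_merge_map named character vector mapping every training class
#'   to an evaluation class. Defaults to the identity map (no merging).
#' @return An object of class `label_taxonomy` with elements
#'   `training_classes`, `eval_classes` and `eval_merge_map`.
#' @examples
#' tx <- label_taxonomy(c("band", "segmented", "bare_nucleus", "artifact"),
#'                      c(band = "band", segmented = "segmented",
#'                        bare_nucleus = "debris", artifact = "debris"))
#' tx$eval_classes
#' @export
label_taxonomy <- function(training_classes, eval_merge_map = NULL) {
  training_classes <- as.character(training_classes)
  if (anyDuplicated(training_classes))
    stop("training class names must be unique")
  if (length(training_classes) < 1L)
    stop("at least one training class is required")
  if (is.null(eval_merge_map)) {
    eval_merge_map <- stats::setNames(training_classes, training_classes)
  }
  eval_merge_map <- eval_merge_map[training_classes]
  if (any(is.na(eval_merge_map)))
    stop("eval_merge_map must cover every training class; missing: ",
         paste(training_classes[is.na(eval_merge_map)], collapse = ", "))
  eval_classes <- unique(unname(eval_merge_map))
  structure(
    list(training_classes = training_classes,
         eval_classes = eval_classes,
         eval_merge_map = eval_merge_map),
    class = "label_taxonomy")
}

#' The 17-class bone-marrow taxonomy
#'
#' The standard bone-marrow configuration: 17 training classes covering the
#' erythroid and granulocytic maturation series plus mononuclear cells,
#' mitotic figures, bare nuclei and artifacts. Bare nuclei and artifacts are
#' distinct classes during training but are merged into one class for
#' evaluation, giving 16 evaluation classes.
#'
#' @return A [label_taxonomy()] with 17 training and 16 evaluation classes.
#' @export
bone_marrow_taxonomy <- function() {
  cls <- c("proerythroblast_basophilic_eb", "polychromatic_eb",
           "orthochromatic_eb", "myeloblast", "promyelocyte", "myelocyte",
           "metamyelocyte", "band_neutrophil", "segmented_neutrophil",
           "eosinophil", "basophil_mastocyte", "monocyte", "lymphocyte",
           "plasma_cell", "mitotic_cell", "bare_nucleus", "artifact")
  mm <- stats::setNames(cls, cls)
  mm[c("bare_nucleus", "artifact")] <- "bare_nucleus_artifact"
  label_taxonomy(cls, mm)
}

#' Map labels onto evaluation classes
#'
#' @param labels character vector of training-class labels.
#' @param taxonomy a [label_taxonomy()].
#' @return character vector of evaluation-class labels.
#' @export
merge_labels <- function(labels, taxonomy) {
  stopifnot(inherits(taxonomy, "label_taxonomy"))
  bad <- setdiff(unique(labels), taxonomy$training_classes)
  if (length(bad))
    stop("labels not in taxonomy: ", paste(bad, collapse = ", "))
  unname(taxonomy$eval_merge_map[labels])
}

#' @export
print.label_taxonomy <- function(x, ...) {
  cat("label_taxonomy:", length(x$training_classes), "training classes ->",
      length(x$eval_classes), "evaluation classes\n")
  invisible(x)
}

#' Single-cell image record
#'
#' A lightweight container for one RGB single-cell image. `true_label` is
#' populated only by the synthetic generator and stands for ground truth that
#' selection logic must never read; the simulated examiner is its only
#' consumer.
#'
#' @param id unique image identifier.
#' @param pixels numeric H x W x 3 array with intensities in `[0, 1]`.
#' @param observed_label optional class label (a labeled / teacher candidate).
#' @param true_label optional hidden ground-truth label (synthetic data only).
#' @return An object of class `cell_image`.
#' @export
cell_image <- function(id, pixels, observed_label = NULL, true_label = NULL) {
  d <- dim(pixels)
  if (length(d) != 3L || d[3] != 3L)
    stop("pixels must be an H x W x 3 array")
  if (d[1] < 8L || d[2] < 8L)
    stop("image must be at least 8 x 8 pixels")
  rng <- range(pixels)
  if (rng[1] < 0 || rng[2] > 1)
    stop("pixel intensities must lie in [0, 1]")
  structure(
    list(id = as.character(id), pixels = pixels,
         observed_label = observed_label, true_label = true_label),
    class = "cell_image")
}

#' @export
print.cell_image <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("cell_image '%s' (%d x %d), label: %s\n", x$id, d[1], d[2],
              if (is.null(x$observed_label)) "<unlabeled>" else x$observed_label))
  invisible(x)
}
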