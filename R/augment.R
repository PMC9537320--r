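#' Geometric augmentation of a cell image
#'
#' Applies, in order: rotation about the image centre by an angle drawn
#' uniformly from 0-360 degrees, independent 50% vertical and horizontal
#' flips, and vertical and horizontal shifts each drawn uniformly from
#' -12.5% to +12.5% of the image dimension. The transform is resolved by a
#' single inverse-mapped nearest-neighbour lookup; source coordinates
#' falling outside the image are clamped to the nearest edge pixel, so no
#' empty corners are introduced that could act as spurious class cues.
#'
#' Cell orientation on a slide is arbitrary and cells are not perfectly
#' centred in their crops, which is what this recipe emulates.
#'
#' @param image a [cell_image()].
#' @param shift_frac maximum shift as a fraction of each dimension (0.125).
#' @return an augmented `cell_image` with the same id and labels.
#' @export
augment_image <- function(image, shift_frac = 0.125) {
  stopifnot(inherits(image, "cell_image"))
  angle <- stats::runif(1, 0, 360)
  flips <- stats::runif(2) < 0.5
  shifts <- stats::runif(2, -shift_frac, shift_frac)
  transform_image(image, angle = angle, flip_v = flips[1], flip_h = flips[2],
                  shift_v = shifts[1], shift_h = shifts[2])
}

#' Deterministic rotate / flip / shift transform
#'
#' The worker behind [augment_image()], exposed so tests and callers can
#' apply exact parameters. Shifts are rounded to whole pixels
#' (`round(frac * dimension)`); a positive `shift_v` moves content down and
#' a positive `shift_h` moves it right.
#'
#' @inheritParams augment_image
#' @param angle rotation in degrees, counter-clockwise.
#' @param flip_v,flip_h logical; flip about the horizontal / vertical axis.
#' @param shift_v,shift_h shifts as fractions of height / width.
#' @return a transformed `cell_image`.
#' @export
transform_image <- function(image, angle = 0, flip_v = FALSE, flip_h = FALSE,
                            shift_v = 0, shift_h = 0) {
  stopifnot(inherits(image, "cell_image"))
  px <- image$pixels
  h <- dim(px)[1]; w <- dim(px)[2]
  dy <- round(shift_v * h); dx <- round(shift_h * w)
  cy <- (h + 1) / 2; cx <- (w + 1) / 2
  # output grid -> source coordinates, inverting shift, flips, then rotation
  out <- expand.grid(i = seq_len(h), j = seq_len(w))
  yi <- out$i - dy
  xj <- out$j - dx
  if (flip_v) yi <- (h + 1) - yi
  if (flip_h) xj <- (w + 1) - xj
  th <- angle * pi / 180
  # rotate back by -angle about the centre
  yc <- yi - cy; xc <- xj - cx
  ys <- cos(th) * yc - sin(th) * xc + cy
  xs <- sin(th) * yc + cos(th) * xc + cx
  si <- pmin(pmax(round(ys), 1L), h)
  sj <- pmin(pmax(round(xs), 1L), w)
  new_px <- array(0, dim = dim(px))
  for (ch in 1:3) {
    plane <- px[, , ch]
    new_px[, , ch] <- matrix(plane[cbind(si, sj)], nrow = h, ncol = w)
  }
  cell_image(image$id, new_px, observed_label = image$observed_label,
             true_label = image$true_label)
}
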