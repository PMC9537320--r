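#' Synthetic cell-class specification
#'
#' Synthetic classes are parameterized the way morphological grading
#' criteria distinguish real granulocyte maturation stages: by the
#' elongation (major/minor axis ratio) and lobation of the nucleus. This
#' deliberately creates tunable "hard" class pairs (e.g. axis ratios 2.8 vs
#' 3.2, either side of a 3:1 criterion) so that margin-based selection has
#' genuinely ambiguous images to prefer.
#'
#' @param name class name.
#' @param nucleus_axis_ratio major/minor axis ratio of the nucleus (>= 1).
#' @param n_lobes number of nuclear lobes (>= 1).
#' @param nucleus_hue,cytoplasm_hue hues in `[0, 1]` (HSV) of nucleus and
#'   cytoplasm.
#' @param noise_sd standard deviation of additive Gaussian pixel noise.
#' @return an object of class `synth_class_spec`.
#' @export
synth_class_spec <- function(name, nucleus_axis_ratio = 1, n_lobes = 1L,
                             nucleus_hue = 0.75, cytoplasm_hue = 0.58,
                             noise_sd = 0.02) {
  stopifnot(nucleus_axis_ratio >= 1, n_lobes >= 1L, noise_sd >= 0,
            nucleus_hue >= 0, nucleus_hue <= 1,
            cytoplasm_hue >= 0, cytoplasm_hue <= 1)
  structure(list(name = as.character(name),
                 nucleus_axis_ratio = nucleus_axis_ratio,
                 n_lobes = as.integer(n_lobes),
                 nucleus_hue = nucleus_hue, cytoplasm_hue = cytoplasm_hue,
                 noise_sd = noise_sd),
            class = "synth_class_spec")
}

#' Six default synthetic classes echoing a neutrophil maturation series
#'
#' Round-nucleus through elongated and lobed classes, including the
#' deliberately ambiguous metamyelocyte-like (ratio 2.8) vs band-like
#' (ratio 3.2) pair either side of the 3:1 elongation criterion.
#'
#' @return list of six [synth_class_spec()]s.
#' @export
default_class_specs <- function() {
  list(
    synth_class_spec("round_nucleus", 1.0, 1L, nucleus_hue = 0.75, cytoplasm_hue = 0.55),
    synth_class_spec("oval_nucleus", 1.8, 1L, nucleus_hue = 0.95, cytoplasm_hue = 0.85),
    synth_class_spec("meta_like", 2.8, 1L, nucleus_hue = 0.68, cytoplasm_hue = 0.12),
    synth_class_spec("band_like", 3.2, 1L, nucleus_hue = 0.68, cytoplasm_hue = 0.12),
    synth_class_spec("bilobed", 1.4, 2L, nucleus_hue = 0.55, cytoplasm_hue = 0.30),
    synth_class_spec("trilobed", 1.6, 3L, nucleus_hue = 0.05, cytoplasm_hue = 0.45))
}

hsv_rgb <- function(h, s, v) {
  as.numeric(grDevices::col2rgb(grDevices::hsv(h, s, v))) / 255
}

render_cell <- function(spec, size, rng_unused = NULL) {
  # geometry in [0,1]^2 coordinates; cytoplasm disc centred with radius 0.42
  cell_r <- 0.42
  nuc_area <- 0.22 * pi * cell_r^2 / spec$n_lobes
  b <- sqrt(nuc_area / (pi * spec$nucleus_axis_ratio))   # minor semi-axis
  a <- b * spec$nucleus_axis_ratio                        # major semi-axis
  extent <- a * (1 + 0.62 * (spec$n_lobes - 1))          # reach along the major axis
  if (extent > cell_r)
    stop("nucleus does not fit inside the cell for spec '", spec$name,
         "' (axis ratio ", spec$nucleus_axis_ratio, ", ", spec$n_lobes, " lobes)")
  theta <- stats::runif(1, 0, pi)
  jitter <- stats::runif(2, -0.04, 0.04)
  g <- seq(0.5 / size, 1 - 0.5 / size, length.out = size)
  xy <- expand.grid(y = g, x = g)
  cx <- 0.5 + jitter[1]; cy <- 0.5 + jitter[2]
  in_cell <- (xy$x - cx)^2 + (xy$y - cy)^2 <= cell_r^2
  # lobes placed along the rotated major axis
  nuc <- rep(FALSE, nrow(xy))
  if (spec$n_lobes == 1L) centers <- 0
  else centers <- seq(-1, 1, length.out = spec$n_lobes) * a * (spec$n_lobes - 1) * 0.62
  for (off in centers) {
    ox <- cx + off * cos(theta); oy <- cy + off * sin(theta)
    u <- (xy$x - ox) * cos(theta) + (xy$y - oy) * sin(theta)
    v <- -(xy$x - ox) * sin(theta) + (xy$y - oy) * cos(theta)
    nuc <- nuc | ((u / a)^2 + (v / b)^2 <= 1)
  }
  nuc <- nuc & in_cell
  bg_col <- c(0.92, 0.91, 0.90)
  cyt_col <- hsv_rgb(spec$cytoplasm_hue, 0.35, 0.85)
  nuc_col <- hsv_rgb(spec$nucleus_hue, 0.75, 0.35)
  px <- array(0, c(size, size, 3L))
  for (ch in 1:3) {
    plane <- rep(bg_col[ch], nrow(xy))
    plane[in_cell] <- cyt_col[ch]
    plane[nuc] <- nuc_col[ch]
    px[, , ch] <- matrix(plane, size, size)
  }
  if (spec$noise_sd > 0) {
    px <- px + stats::rnorm(length(px), 0, spec$noise_sd)
    px <- pmin(pmax(px, 0), 1)
  }
  px
}

#' Generate a labeled synthetic image set
#'
#' Renders `n_per_class` images for every class spec: a uniform background,
#' a cytoplasm disc with small random centre jitter, and a nucleus built
#' from `n_lobes` ellipses of the spec's axis ratio at a random orientation,
#' plus Gaussian pixel noise. Every image carries its hidden `true_label`
#' (read only by the simulated examiner, never by selection logic).
#' Reproducible under `seed`.
#'
#' @param specs list of [synth_class_spec()]s (at least 2).
#' @param n_per_class images per class.
#' @param image_size square side length in pixels (>= 32).
#' @param seed integer seed.
#' @param id_prefix prefix for generated image ids.
#' @return list of [cell_image()]s, `n_per_class` per class, in class-major
#'   order.
#' @export
generate_dataset <- function(specs, n_per_class, image_size = 32L, seed = 1L,
                             id_prefix = "syn") {
  stopifnot(length(specs) >= 2L, image_size >= 32L, n_per_class >= 1L)
  out <- vector("list", length(specs) * n_per_class)
  k <- 0L
  with_seed(seed, {
    for (spec in specs) {
      for (i in seq_len(n_per_class)) {
        k <- k + 1L
        px <- render_cell(spec, image_size)
        out[[k]] <- cell_image(sprintf("%s_%s_%04d", id_prefix, spec$name, i),
                               px, true_label = spec$name)
      }
    }
  })
  out
}

#' Simulated examiner (oracle)
#'
#' Emulates the human examiners who confirm pseudo labels (confirmation
#' queries) or label margin-sampled images from scratch (labeling queries).
#' The oracle looks labels up in the generator's hidden ground truth and is
#' imperfect in two configurable ways: with probability `reject_rate` it
#' declines an image as too difficult (the image is not added), and with
#' probability `error_rate` it returns a uniformly wrong label. Responses
#' are reproducible given the seed and query order.
#'
#' @param images list of [cell_image()]s, all carrying `true_label`.
#' @param error_rate probability of a wrong label on an answered query.
#' @param reject_rate probability of rejecting/skipping a query.
#' @param seed integer seed.
#' @return an oracle handle of class `simulated_oracle`.
#' @export
make_simulated_oracle <- function(images, error_rate = 0, reject_rate = 0,
                                  seed = 1L) {
  stopifnot(error_rate >= 0, reject_rate >= 0, error_rate + reject_rate <= 1)
  truths <- vapply(images, `[[`, character(1), "true_label")
  if (any(is.na(truths) | !nzchar(truths)))
    stop("every image must carry a true_label")
  ids <- vapply(images, `[[`, character(1), "id")
  env <- new.env(parent = emptyenv())
  env$truth <- stats::setNames(truths, ids)
  env$classes <- sort(unique(truths))
  env$error_rate <- error_rate
  env$reject_rate <- reject_rate
  env$rng_state <- NULL
  with_seed(seed, env$rng_state <- get(".Random.seed", envir = globalenv()))
  structure(env, class = "simulated_oracle")
}

#' @export
print.simulated_oracle <- function(x, ...) {
  cat(sprintf("simulated_oracle: %d images, error_rate %.3g, reject_rate %.3g\n",
              length(x$truth), x$error_rate, x$reject_rate))
  invisible(x)
}

#' Query an oracle
#'
#' The single entry point selection code uses. For a confirmation query
#' (`type = "cst"`, `pseudo_label` given) the verdict is one of `confirm`,
#' `relabel` (with the corrected label) or `reject`; for a labeling query
#' (`type = "al"`) it is `label` (with the label) or `skip`.
#'
#' @param oracle an oracle handle.
#' @param image_id id of the queried image.
#' @param pseudo_label the classifier's pseudo label (confirmation queries).
#' @param type `"cst"` or `"al"`.
#' @return list with `verdict` and, where applicable, `label`.
#' @export
oracle_query <- function(oracle, image_id, pseudo_label = NULL,
                         type = c("cst", "al")) {
  UseMethod("oracle_query")
}

#' @export
oracle_query.simulated_oracle <- function(oracle, image_id, pseudo_label = NULL,
                                          type = c("cst", "al")) {
  type <- match.arg(type)
  idx <- match(image_id, names(oracle$truth))
  if (is.na(idx)) stop("unknown image id '", image_id, "'")
  truth <- oracle$truth[[idx]]
  # private RNG stream: swap in, draw, swap out
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  assign(".Random.seed", oracle$rng_state, envir = globalenv())
  u <- stats::runif(2)
  wrong_pick <- sample(max(length(oracle$classes) - 1L, 1L), 1L)
  oracle$rng_state <- get(".Random.seed", envir = globalenv())
  if (has_old) assign(".Random.seed", old, envir = globalenv())
  else rm(".Random.seed", envir = globalenv())

  if (u[1] < oracle$reject_rate)
    return(list(verdict = if (type == "cst") "reject" else "skip"))
  answer <- truth
  if (u[2] < oracle$error_rate) {
    pool <- setdiff(oracle$classes, truth)
    if (length(pool)) answer <- pool[wrong_pick %% length(pool) + 1L]
  }
  if (type == "al") return(list(verdict = "label", label = answer))
  if (!is.null(pseudo_label) && identical(answer, pseudo_label))
    list(verdict = "confirm")
  else
    list(verdict = "relabel", label = answer)
}

#' Bundled 25-round reference history (three strategy arms)
#'
#' The published round-by-round record of the reference bone-marrow
#' experiment: test accuracy and cumulative teacher-pool size (DATA_Count)
#' after each of 25 semi-supervised rounds, for the confirmed self-training
#' (CST), active-learning (AL) and combined (CST+AL) arms. All three arms
#' start from the same 425-image seed pool (25 images x 17 classes).
#'
#' @return a [round_history()] with arms `cst_al`, `cst` and `al`.
#' @export
table1_fixture <- function() {
  path <- system.file("extdata", "table1_round_history.csv", package = "sslcyto",
                      mustWork = TRUE)
  df <- utils::read.csv(path)
  long <- do.call(rbind, lapply(
    c(cst_al = "CST_AL", cst = "CST", al = "AL"), function(suf) {
      data.frame(round = df$round,
                 accuracy = df[[paste0("Accuracy_", suf)]],
                 data_count = df[[paste0("DATA_Count_", suf)]])
    }))
  long$arm <- rep(c("cst_al", "cst", "al"), each = nrow(df))
  round_history(long[, c("arm", "round", "accuracy", "data_count")],
                n_classes = 17L)
}
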