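---
title: "Semi-supervised labeling with confirmed self-training and margin sampling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Semi-supervised labeling with confirmed self-training and margin sampling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sslcyto)
```

## The procedure

`sslcyto` implements a human-in-the-loop semi-supervised labeling loop for
single-cell image classification. One *round* is:

1. **Subsample** the unlabeled pool (`unlabeled_sample_size`, 5000 at full
   scale) so the examiner-facing candidate lists stay manageable.
2. **Score** the subsample with the current classifier, producing one
   probability vector per image over the training classes.
3. **Select** candidates:
   - *Confirmed self-training (CST)*: rows whose top probability is at
     least the confidence threshold θ (inclusive). The argmax class is the
     pseudo label; the examiner confirms it, corrects it, or rejects the
     image. Rejected images are not added and stay unlabeled.
   - *Margin-sampling active learning (AL)*: rows whose top-two gap
     p₁ − p₂ is strictly below the margin m. The examiner labels these
     from scratch or skips them.
   - *CST + AL*: both rules on the same prediction run. When
     2θ − 1 ≥ m the candidate sets cannot overlap, since p₁ ≥ θ implies
     p₂ ≤ 1 − θ and hence a margin of at least 2θ − 1. At the reference
     settings (θ = 0.9, m = 0.2) the guarantee holds with room to spare.
4. **Update pools**: approved additions move from the unlabeled to the
   labeled pool, stamped with the round number. The labeled pool only
   grows; images the examiner declined remain unlabeled and may be
   resampled in later rounds (only *added* images are subtracted from the
   unlabeled pool).
5. **Balance** the training set: a class holding more than `per_class_cap`
   (1000) records sheds earlier-round records down to the cap, oldest
   rounds first. Records from the current round are never deleted, so
   every new label is trained on at least once — a class whose newest
   additions alone exceed the cap is deliberately left above it.
6. **Retrain** with a warm start from the previous round's weights
   (SGD with momentum, learning rate `lr_first` = 0.01 in round one and
   `lr_later` = 0.005 afterwards, 250 epochs per round at full scale), and
   score the held-out test set for the history.

The loop begins only after the seed model (trained on
`initial_per_class` = 25 images per class at full scale) reaches the
validation gate of 80% accuracy, inclusive; initial training is retried
with reseeded weights up to `gate_retries` times, then the run aborts.
Validation images are labeled once and reused unchanged every round; the
test set is disjoint from everything and only feeds the history's
accuracy column.

An important bookkeeping distinction: the *labeled pool* (whose size is
the `data_count` history column) grows monotonically and is never pruned,
while the *per-round training set* is the balanced view of it. This is
the only reading under which a 1000-per-class cap coexists with labeled
pools that grow far beyond `1000 × classes`, as the reference history's
final counts do.

## Two confidence thresholds

The confirmation threshold is 0.99 when CST runs alone and 0.9 inside
CST + AL; both appear in the reference protocol, and
`experiment_config()` defaults accordingly per strategy. Both are
configurable. If a user configures thresholds that break the disjointness
precondition (2θ − 1 < m), the implementation lets the confirmation route
claim contested images — its verdict carries more model confidence — and
warns rather than failing.

## The reference classifier

The reference model is a compact squeeze-and-excitation convolutional
network: four stages, each stage two 3×3 convolutions (stride 1, pad 1)
with batch normalization and ReLU, then an SE block (global average
pool → bottleneck of ratio `se_reduction` → sigmoid gate on the stage's
channels), then 2×2 max pooling; global average pooling and a softmax
head follow stage four. That is eight convolution layers in total. Default
stage widths are 32/64/128/256 with `se_reduction` 16; these widths are
package defaults chosen as standard SE-network idiom, not measurements of
any particular published figure, and are configurable. The optimizer is
SGD with momentum 0.9 (the conventional default; the value is a package
choice), batch size 32, categorical cross-entropy — the only conventional
loss for a softmax multiclass head.

The network, including backpropagation through batchnorm, the SE gates
and pooling, is implemented natively in R: convolutions are expressed as
im2col patch matrices multiplied by `(k²·C_in) × C_out` weight matrices,
so the heavy arithmetic is BLAS matrix multiplication. The test suite
verifies every layer's analytic gradient against central finite
differences on a miniature configuration (conv biases are excluded there:
a bias feeding a batchnorm has an exactly zero gradient, which finite
differences confirm trivially). Training is reproducible: weight
initialization, shuffling and augmentation draws all derive from the
configured seeds, and inference uses frozen running batch statistics, so
`predict_proba()` is deterministic for a fixed model.

The classifier is a *contract*, not a hard dependency of the loop: any
object with `train_round()` and `predict_proba()` methods can drive
`run_experiment()`. The bundled `moment_classifier` (multinomial logistic
regression on ten morphometric image features, fitted via `nnet`) is that
contract's fast second implementation, used heavily in the tests; the
network remains the reference.

## Augmentation

Every training image is augmented per epoch: rotation uniform in 0–360°,
independent 50% vertical/horizontal flips, and vertical/horizontal shifts
uniform in ±12.5% of the image dimension. Cell orientation on a slide is
arbitrary, which is what the recipe emulates. The transform is a single
inverse-mapped nearest-neighbour affine warp; source coordinates outside
the image clamp to the nearest edge pixel. Edge-clamp fill was chosen
over zero fill because black corners introduced by rotation would be a
spurious, augmentation-correlated class cue. Shifts round to whole
pixels; with nearest-neighbour resampling, axis-aligned compositions
(180° rotation plus both flips, integer shifts) are exact identities,
which the tests exploit.

## The synthetic generator and simulated examiner

Real stained bone-marrow images cannot ship with a package, so the
generator renders controllable stand-ins: a uniform background, a
cytoplasm disc with small centre jitter, and a nucleus built from
`n_lobes` ellipses of a specified major/minor axis ratio at random
orientation, plus Gaussian pixel noise. Classes are parameterized the way
morphological grading criteria actually separate granulocyte maturation
stages — by nuclear elongation and lobation; the default six classes
include a deliberately ambiguous pair at ratios 2.8 vs 3.2, either side
of a 3:1 elongation criterion, which *shares identical colors* and
differs only in shape. The other classes carry distinct nucleus/cytoplasm
hue signatures, as distinct real cell classes do; with ten images per
class a desk-scale model cannot learn shape alone, and the generator's
goal is classes that are separable except where ambiguity is wanted. A
moment-based axis-ratio measurement (`mask_axis_ratio()`) recovers the
design ratios from noise-free renders, and class separability grows
monotonically with the ratio gap — both are tested.

What the generator does *not* emulate: staining variability, touching or
overlapping cells, focus artifacts, class imbalance in the unlabeled
stream, and intra-class morphological heterogeneity. Tests passing on
synthetic data therefore validate the *loop machinery* — selection rules,
pool accounting, balancing, determinism, examiner protocol — not
real-image accuracy. The reference protocol's full-scale accuracies
require the original hospital image set and are out of reach here by
design.

The simulated examiner answers confirmation queries (confirm / relabel /
reject) and labeling queries (label / skip) from the generator's hidden
ground truth, which selection logic never reads. Two imperfection knobs:
`reject_rate` (image declined as too difficult) and `error_rate`
(uniformly wrong label returned). The examiner keeps a private RNG stream,
so its responses replay exactly under a fixed seed and query order
regardless of surrounding code.

## Numerical choices and degenerate inputs

- Probability rows must sum to 1 within 1e−6 (construction fails naming
  the offending row). Argmax ties break toward the lowest class index.
- Threshold boundaries follow the stated semantics — CST inclusive
  ("0.99 or more"), AL strict ("less than") — with a 1e−9 tolerance so
  that decimal-printed boundary values (e.g. a margin of exactly 0.2
  arising as 0.6 − 0.4 in floating point) behave as printed.
- Balancing tie-breaks within a round are uniform draws under the
  experiment seed; whether the reference procedure deleted old records
  randomly or deterministically is unstated, so the package fixes a
  reproducible rule: oldest round first, random within a round.
- An empty unlabeled pool ends the loop cleanly with a warning and a
  partial history; an oracle failure on one image is logged and treated
  as a rejection of that image only.
- Per-round RNG streams (subsampling, balancing, training) derive from
  the master seed, so arms sharing a seed see identical unlabeled
  subsamples — that is what makes paired arm comparisons meaningful.

## Problem sizes used in the tests

The suite runs everything at desk scale, chosen so the full loop with the
convolutional reference model stays in CPU-minutes: six synthetic classes
with 10 seed, 8 validation, 8 test and 30 unlabeled images each at
32 px; stage widths 6/12/12/24 with SE reduction 4; batch size 10;
20 epochs per round for 3 rounds; learning rates 0.01/0.005 as in the
full protocol. At that scale the seed model clears the 80% gate and the
end-to-end run is exactly reproducible under a fixed seed. Structural
driver tests use the feature-based backend, which is two orders of
magnitude faster; selection, pooling and evaluation tests are
backend-free.

## Known limitations

- The native network is CPU-bound and desk-scale by construction; it is
  not a tool for training on hundreds of thousands of full-resolution
  images, and no GPU path is provided.
- `growth_statistics()` and `summarize_history()` are descriptive only;
  inferential statistics over round histories (ANOVA and relatives) are
  out of scope.
- The examiner model is deliberately simple (uniform error, uniform
  reject); systematic, class-dependent examiner confusion is not
  modeled.
- Evaluation-class merging supports many-to-one maps only.
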