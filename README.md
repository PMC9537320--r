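# sslcyto

Iterative semi-supervised labeling for single-cell image classification.

## The problem

Training an automatic classifier for bone-marrow (or peripheral-blood) cell
images needs tens of thousands of expert-labeled single-cell crops, and
expert labeling time is the binding constraint. Semi-supervised learning
attacks this by letting a model trained on a small seed set propose labels
for unlabeled images, with a human examiner kept in the loop. `sslcyto`
implements that loop as a reusable, tested R pipeline built around two
candidate-selection strategies and their combination:

- **Confirmed self-training (CST).** Images whose top predicted class
  probability reaches a confidence threshold θ (0.99 standalone, 0.9 in the
  combined strategy) get their pseudo label shown to an examiner, who
  confirms it, corrects it, or rejects the image. Plain self-training
  without confirmation degrades as mislabeled images accumulate; the
  confirmation step is what makes the scheme stable.
- **Margin-sampling active learning (AL).** Images where the gap between
  the top-two class probabilities p₁ − p₂ falls below a margin m (0.2) are
  the ones the classifier is least decided about; the examiner labels them
  from scratch.
- **CST + AL.** Both rules applied in parallel to the same prediction run.
  Whenever 2θ − 1 ≥ m the two candidate sets are provably disjoint
  (p₁ ≥ θ forces p₁ − p₂ ≥ 2θ − 1), so each image is handled once.

Each round: subsample the unlabeled pool (5000 images at full scale),
score it with the current model, select and verify candidates, move
approved additions into the labeled pool, rebuild a class-balanced
training set (per-class cap 1000, newest additions always kept so every
new label is trained on at least once), retrain with a warm start
(SGD + momentum, learning rate 0.01 first round then 0.005), and log
test accuracy and pool size. The loop starts only once the seed model
clears an 80% validation gate, and runs 25 rounds at full scale.

The reference classifier is a compact squeeze-and-excitation convolutional
network — four stages of two 3×3 convolutions (batchnorm + ReLU), an SE
block per stage, 2×2 max-pooling, global average pooling and a softmax
head — implemented natively in R with BLAS-backed im2col convolutions and
verified against finite-difference gradients. The classifier is a
swappable contract (`train_round()` / `predict_proba()`); a fast
feature-based multinomial-logistic backend is included for cheap
experimentation, and everything outside the classifier is backend-agnostic.

Because real bone-marrow image sets are not redistributable, the package
ships a synthetic generator of morphologically parameterized cell classes
(nucleus elongation and lobe count echo the axis-ratio criteria used to
grade granulocyte maturation, including a deliberately ambiguous pair at
ratios 2.8 vs 3.2) and a simulated examiner with configurable error and
rejection rates, so the whole pipeline is testable end to end.

## Worked example

The bundled 25-round reference history (three strategy arms over 17 cell
classes, 425 seed images) summarizes to:

```r
library(sslcyto)
summarize_history(table1_fixture(), expected_rounds = 25)
#>      arm n_rounds mean_accuracy sem_accuracy best_accuracy final_count per_class_mean_final
#> 1     al       25        0.9046     0.007512        0.9413        3682                216.6
#> 2    cst       25        0.9006     0.005804        0.9437       40518               2383.4
#> 3 cst_al       25        0.9358     0.007498        0.9762       47843               2814.3
```

Read: over 25 rounds the combined strategy grew the labeled pool from 425
to 47,843 images and reached the best test accuracy (0.976); confirmation
alone collected 11× more labels than margin sampling alone (40,518 vs
3,682) for essentially the same accuracy, so label volume per se is not
what improves the model.

A desk-scale synthetic run of the combined strategy (6 classes, 10 seed
images each, 32 px, fast backend, perfect oracle):

```r
cfg <- experiment_config(strategy = "cst_al", rounds = 3, epochs_per_round = 5,
                         initial_per_class = 10, validation_per_class = 8,
                         test_per_class = 8, unlabeled_sample_size = 120,
                         backend = "moment", input_size = 32, seed = 11)
data <- prepare_synthetic_experiment(default_class_specs(), cfg, unlabeled_per_class = 30)
oracle <- make_simulated_oracle(data$images, seed = 11)
run_experiment(cfg, data, oracle)$table
#>      arm round accuracy data_count
#> 1 cst_al     1        1         60
#> 2 cst_al     2        1        174
#> 3 cst_al     3        1        236
```

The pool grows 60 → 174 → 236 as confident and ambiguous candidates are
approved each round (the synthetic classes are easy for the feature
backend, hence accuracy 1.0 throughout; the convolutional backend shows
the rising-accuracy trajectory).

A thin CLI wraps the same functions: `exec/sslcyto synth|run|stats`.

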