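# enhancerPRS

Tissue-specific enhancer prediction from DNA sequence with a
**pretraining–retraining strategy** (PRS).

## The problem

Enhancers are distal cis-regulatory elements, and most act only in
particular cells or tissues. Sequence-based deep learning handles the
generic "enhancer vs not" task well, but the *tissue-specific* task breaks
it: one tissue typically has only a few hundred positive examples, and a
network trained from scratch on a small, 1:10-imbalanced set tends to
collapse to the majority class (specificity ≈ 1, sensitivity ≈ 0).

PRS splits training in two:

1. **Pretrain** one hybrid convolutional / bidirectional-GRU network on a
   large pool of broadly active ("housekeeping") enhancers, selecting the
   checkpoint epoch that minimizes an L1-penalized validation objective

   `objective_va = crossentropy_va + λ₁‖M‖₁ + λ₂‖WU‖₁ + λ₃‖WM‖₁`

   where `M` is the convolution filter bank, `WU` the recurrent GRU weight
   matrices and `WM` the dense-layer weights.
2. **Retrain** from that checkpoint for a short fixed budget (20 epochs)
   on each tissue's own small dataset. Warm-started models inherit working
   motif detectors and largely avoid the majority-class collapse.

The network is Conv(valid, stride 1) → ReLU → non-overlapping MaxPool →
Dropout → Bi-GRU (final states of both directions concatenated) →
Dense(32, ReLU) → sigmoid, with ŷ = 1 / (1 + e^(−NN)). Performance on
imbalanced data is summarized by GM = √(Sens·Spec) and the Matthews
correlation, alongside AUC/AUPRC.

The package also ships the full dataset-construction pipeline (TPM-based
positive selection from an enhancer activity matrix, 1000 bp length
fixing, greedy redundancy reduction, intergenic negative sampling), an
evaluation/cross-validation module, a two-stage hyperparameter grid
search, and a synthetic motif-planting simulator so everything is testable
without genome downloads. The forward/backward passes are compiled
(RcppArmadillo) and verified against finite differences.

## Worked example

A complete desk-scale run on synthetic data (200 bp fast profile; ~1 min
on one CPU):

```r
library(enhancerPRS)

spec <- synthetic_spec(length = 200)          # 600 pretraining positives,
pre  <- generate_pretraining_set(spec, seed = 3)   # 3 tissues x 200, 1:10
pre
#> sequence set: 6600 records of length 200 bp (600 positive / 6000 negative)

cfg <- network_config(filter_number = 16, filter_length = 11, pool_size = 8,
                      gru_units = 16, input_length = 200)
fit <- pretrain(pre, cfg, objective_config(max_epochs = 30, seed = 1))
fit$run$selected_epoch
#> [1] 29
fit$report
#> Sens 0.560  Spec 0.994  Prec 0.903  ACC 0.955  MCC 0.691  GM 0.746  AUC 0.927  AUPRC 0.794

tis  <- generate_tissue_set(spec, "tissueA")
warm <- retrain(fit$run$params, tis, epochs = 20, obj_cfg = objective_config(seed = 1))
cold <- ab_initio(tis, cfg, epochs = 20, obj_cfg = objective_config(seed = 1))
warm$report
#> Sens 0.500  Spec 0.994  Prec 0.889  ACC 0.951  MCC 0.645  GM 0.705  AUC 0.904  AUPRC 0.748
cold$report
#> Sens 0.000  Spec 1.000  Prec 0.000  ACC 0.912  MCC 0.000  GM 0.000  AUC 0.819  AUPRC 0.290
```

The pretrained model separates held-out enhancers (AUC 0.93); after
20 warm-start epochs the tissue model recovers half of the tissue
positives (GM 0.705), while the identically budgeted ab-initio model
predicts *no* positives at the 0.5 threshold (GM 0) even though it ranks
reasonably (AUC 0.82) — the imbalance collapse PRS is designed to avoid.
`prs_benchmark()` repeats this comparison over seeds and tissues and
`compare_strategies()` tests the paired per-tissue difference one-sided.

A thin command-line wrapper covers the same pipeline
(`simulate`, `prepare-pretrain`, `prepare-tissue`, `pretrain`, `retrain`,
`ab-initio`, `grid-search`, `evaluate`, `compare`):

```sh
Rscript "$(Rscript -e 'cat(system.file("cli/enhancer-prs", package="enhancerPRS"))')" \
    simulate --out sim --seed 3 --fast
```

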