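---
title: "Pretraining-retraining for tissue-specific enhancer prediction: model and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pretraining-retraining for tissue-specific enhancer prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(enhancerPRS)
```

## The problem

Enhancers are distal cis-regulatory elements, and most of them act in a
cell- or tissue-specific way. Discriminating enhancer sequence from
non-enhancer sequence genome-wide (the generic prediction task) is well
served by convolutional sequence models, but the tissue-specific task is
not: a single tissue or cell line typically contributes only a few hundred
positive examples, far fewer than the number of parameters in any modern
sequence network, so models trained from scratch on one tissue overfit or,
on heavily imbalanced data, collapse to the majority class.

This package implements a two-stage *pretraining-retraining* strategy
(PRS). One network is first trained on a large pool of broadly active
("housekeeping") enhancers — sequences whose enhancer RNA expression is
detected across essentially all assayed tissues — to learn generic enhancer
sequence features. For each individual tissue, training then *resumes from
that converged checkpoint* for a small, fixed number of epochs on the
tissue's own small dataset. The pretrained weights act as an informed
initialization, so the tissue model needs only a short retraining budget
and largely avoids the majority-class collapse that defeats ab-initio
training at this sample size.

## The network

The classifier is a hybrid convolutional / bidirectional-recurrent network
over one-hot DNA (channels A, C, G, T; ambiguous N encodes as an all-zero
row):

1. **Convolution** (`filter_number` filters of `filter_length` bp, valid,
   stride 1). The filter bank `M` plays the role of a learned motif
   scanner.
2. **ReLU**, then **non-overlapping max pooling** of width `pool_size`;
   remainder positions are truncated, so the pooled length is
   `floor((L - m + 1) / p)`.
3. **Dropout** on the pooled features (training only; inverted dropout, so
   inference needs no rescaling).
4. A **bidirectional GRU** over the pooled position axis; each position
   contributes its vector of filter activations. Update rule per gate:
   `h_t = (1 - z_t) * h_{t-1} + z_t * hcand_t`, with update gate `z`,
   reset gate `r` and candidate memory `hcand`. The final hidden states of
   the forward and reverse passes are concatenated. The recurrent weight
   matrices form the penalized group `WU`. The bidirectional pass is also
   why no reverse-complement data augmentation is performed: strand
   symmetry is the recurrent layer's job.
5. A **dense layer of 32 ReLU units** (weights `WM`), then a scalar
   projection and a **sigmoid**, giving a score strictly inside (0, 1).

The forward and backward passes are implemented in compiled code
(RcppArmadillo); all randomness — initialization, minibatch shuffling,
dropout masks — is drawn from R's RNG so every run is reproducible from a
single integer seed. The analytic gradients are verified against central
finite differences in the test suite.

## Objective and epoch selection

Training minimizes mean binary cross-entropy plus elementwise L1 penalties
on the three weight groups:

```
objective = crossentropy + lambda1*|M|_1 + lambda2*|WU|_1 + lambda3*|WM|_1
```

Biases and the final scalar projection are excluded from all three norms
(standard practice; the penalized groups are the named weight matrices).
The same penalized form evaluated on a held-out validation split is the
*epoch selection* criterion for pretraining: after every epoch the
validation objective is recorded, and the returned checkpoint is the epoch
that minimizes it — never simply the last epoch. The L1 terms are applied
to the training loss as well as the validation objective, so the quantity
used for selection is the quantity being optimized.

Retraining deliberately does **not** use epoch selection: the FANTOM-epN /
None-epN protocol is defined by a fixed epoch budget, so `retrain()` runs
exactly `epochs` epochs (0 epochs returns the checkpoint unchanged, an
invariant the tests assert). A validation-selected variant is available via
`select_epoch = TRUE`. By default retraining updates *all* parameter
groups; the `freeze` argument covers the stricter reading in which only
part of the network is revisited.

Defaults and their reasons:

| parameter | default | rationale |
|---|---|---|
| `filter_number`, `filter_length`, `pool_size` | 64, 23 bp, 8 | the grid-search optimum at full scale (the two-stage search over filter number x length, then length x pool size, is implemented in `grid_search()`) |
| `gru_units` | 32/direction | matches the 32-unit dense head; configurable |
| `dropout_rate` | 0.2 | a conventional mild rate for the pooled features |
| `lambda1..3` | 1e-6 | small enough not to dominate cross-entropy on desk-scale data |
| optimizer | adaptive moments, lr 1e-3, batch 64 | standard choice for this model family; all configurable |
| threshold | 0.5 | score >= threshold predicts enhancer |
| retraining budget | 20 epochs | the budget study's optimum: shorter budgets underlearn the new tissue, 50+ epochs begin to overfit |

Class imbalance is handled by plain (unweighted) cross-entropy. This is a
deliberate choice: the characteristic failure of ab-initio training on
1:10 data — high specificity, near-zero sensitivity — is part of the
phenomenon the package studies, and weighting it away would hide it.
Optional class weights can be emulated by resampling the input set.

## Evaluation

`eval_metrics()` reports sensitivity, specificity, precision, accuracy and
Matthews correlation from confusion counts at the stated threshold, plus
two geometric-mean variants: `GM = sqrt(Sens * Spec)` and
`GM_pr = sqrt(Precision * Recall)`. The square-root-of-Sens-times-Spec
form is the reported default because it is the definition that the
published evaluation tables in this literature actually satisfy
(reconstructing the table rows from their own printed rates reproduces the
GM cells to 3 decimal places under `GM_ss`, and not under `GM_pr`; the
acceptance checks record this). Conventions for degenerate counts: MCC
with a zero denominator factor is 0, precision with no positive calls
is 0.

AUC is computed as the Mann-Whitney statistic via midranks (tested against
exhaustive pair enumeration and an established ROC package), AUPRC as the
step-curve area of a descending-score sweep with ties grouped.
`cross_validate()` runs stratified k-fold evaluation with an inner
validation split carved from the training folds for epoch selection, and
aggregates folds by unweighted means. `compare_strategies()` performs the
per-tissue comparison as a *paired* one-sided t test on matched tissue
values (the pairing across tissues is the natural design here; an unpaired
Welch variant is available). Zero-variance differences are reported as a
degenerate branch rather than an error.

## Dataset construction

`parse_activity_matrix()` reads a regions-by-samples TPM table with
BED-style `chrom:start-end` identifiers (0-based, half-open everywhere).
Two filters derive positive sets from it:

* **Pretraining pool**: regions whose minimum *nonzero* TPM across all
  samples is at least 0.08 — enhancers with detectable activity wherever
  they are expressed at all. All-zero rows are excluded.
* **Tissue sets**: regions whose TPM in the named sample is *strictly*
  greater than 0.8, the upper-quartile activity level. The strict
  inequality follows the "larger than the cutoff guarantees activity"
  reading of the selection rule.

`fix_length()` standardizes accepted regions (at least 100 bp) to
1000 bp windows centred on the region midpoint, `floor((start + end)/2)`;
centring preserves the bidirectional-transcription midpoint of the eRNA
signal, and windows that would overrun a chromosome end are dropped rather
than clipped. `reduce_redundancy()` performs greedy, longest-first
clustering at 0.8 identity, where identity is the matching-base fraction
of the best ungapped offset alignment over the shorter sequence and only
offsets sharing an exact 8-mer are scanned — the same short-word pruning
idea as CD-HIT, without re-implementing its exact heuristics (a
pass-through to an external `cd-hit-est` binary is available when one is
installed). Ties in the longest-first ordering are broken by input order,
so the procedure is deterministic and idempotent. `sample_negatives()`
draws label-0 windows uniformly from the genome minus the supplied
exclusion intervals; windows containing any ambiguous base are rejected
and redrawn, avoiding arbitrary N-encoding effects in training data.

## The synthetic generator

Because full-scale enhancer atlases and reference genomes cannot be
bundled, every stage is testable on generated data with the statistical
structure PRS assumes:

* a large **shared-signal class**: positives carry each of three "shared"
  motifs (widths 8–12) independently with probability 0.8;
* small **tissue classes**: positives carry the same shared motifs *plus*
  one tissue-private motif (probability 0.9);
* negatives are i.i.d. background DNA at GC 0.42 (human-like);
* 600 pretraining positives, 200 positives per tissue, 1:10 imbalance,
  3 tissues, 1000 bp sequences (a 200 bp fast profile is used for
  desk-scale runs).

Motif PWMs concentrate 0.85 probability on the consensus base per
position: sharp enough that the classes are separable by construction (a
plain consensus scanner reaches AUC > 0.8, which the tests certify), soft
enough that a few hundred positives do not trivially saturate learning.
`generate_activity_matrix()` likewise plants ground-truth "housekeeping"
and "tissue-active" rows whose TPM patterns are recovered exactly by the
two selection filters.

What the generator does *not* model: real eRNA expression distributions,
nucleosome positioning, repeat structure, motif grammar (spacing or
orientation preferences), or any correlation between activity level and
sequence content. Passing tests therefore certify the machinery — data
handling, optimization, epoch selection, transfer — not performance on
real genomes.

## Desk-scale study conditions

The benchmark (`prs_benchmark()`) runs the full two-stage strategy at the
fast profile: 200 bp sequences, the default synthetic counts above, a
16-filter / 11 bp / pool-8 / 16-GRU-unit network, pretraining for up to 30
epochs with validation-based selection, then 20-epoch warm-start
retraining versus 20-epoch ab-initio training on each of three tissues
across five seeds. These sizes were chosen as the smallest configuration
at which the warm-start advantage is reliably detectable, and a complete
5-seed benchmark runs in a few minutes on one CPU. The qualitative outcome
mirrors the full-scale finding: ab-initio models at this budget tend to
collapse to the majority class (near-zero sensitivity, hence near-zero
GM), while warm-started models inherit working motif detectors and score
substantially higher on both sensitivity and GM.

## Numerical choices and degenerate inputs

* Max pooling truncates remainder positions; `network_config()` rejects
  configurations whose pooled length would be zero.
* Scores are clipped to `[1e-12, 1 - 1e-12]` inside the loss only; the
  gradient uses the exact sigmoid-cross-entropy form, which is stable.
* A non-finite training loss aborts with the run history attached.
* Confusion ties at the threshold predict positive (`>=` rule).
* `retrain(..., epochs = 0)` is the exact identity on the checkpoint.
* Checkpoints embed a format version and the full configuration; loading
  fails loudly on mismatch.

## Known limitations

* The L1 penalties use a plain subgradient (`sign`) inside the
  adaptive-moment update rather than a proximal step; at the default
  1e-6 weights the difference is negligible, but large penalties will not
  produce exact zeros.
* Redundancy reduction's seeded-offset identity can, in principle, miss a
  above-cutoff ungapped alignment that contains no shared 8-mer; such
  pairs are rare for the 0.8 cutoff and typical sequence lengths.
* The GRU gate parameterization stores input and recurrent matrices
  separately per gate and direction (twelve matrices); coarser
  "six-matrix" descriptions of a bidirectional GRU are a grouping of the
  same quantities, and the L1 group `WU` covers all of them.
* Training is single-threaded by design (reproducibility over speed); the
  desk-scale problem sizes keep this practical.
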