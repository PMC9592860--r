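---
title: "Discriminant embedding plus Transformer classification of scRNA-seq cell types"
author: "ldaformer"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discriminant embedding plus Transformer classification of scRNA-seq cell types}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## Overview

`ldaformer` assigns cell-type labels to single-cell RNA-seq profiles by
supervised learning. The pipeline has three stages:

1. **Preprocessing** — gene-symbol cleaning, per-cell global-scaling
   log-normalisation, removal of rare cell types, optional
   harmonisation of an independently collected train/test pair, and a
   stratified 8:2 split.
2. **Supervised reduction** — shrinkage-regularised linear discriminant
   analysis to `d = k - 1` dimensions for `k` classes, followed by a
   stored positive shift.
3. **Classification** — a per-position token embedding, a Transformer
   encoder with multi-head scaled dot-product attention (optionally
   extended by a single-query decoder summary token), a 1-D
   convolutional feature extractor, and a linear softmax head trained
   with cross-entropy.

This vignette records the modelling assumptions, the defaults and why
they were chosen, the numerical decisions, and what the synthetic-data
tests do and do not demonstrate.

## Preprocessing assumptions

*Normalisation.* Counts are transformed per cell as
`log(1 + x * s / total)`. The scale factor `s` is not dictated by the
method; we adopt the community convention `s = 10^4` and expose it as an
argument. The transform is invariant to multiplying a cell's counts by a
constant, so library-size differences cancel; it does not attempt batch
correction (out of scope).

*Gene cleaning.* Symbols absent from an optional reference list are
dropped, and **every** copy of a duplicated symbol is removed rather
than summed — a repeated symbol cannot be attributed to one locus, and
summing would silently merge distinct loci.

*Rare types.* Cell types below 5‰ of cells are removed together with
their cells. The comparison is strict (`count < 0.005 * n` removed), so
a type sitting exactly on the threshold survives.

*Splitting.* The protocol says only "random"; we stratify by class by
default so that rare types appear on both sides of the split, and make
stratification switchable. A class with fewer than two cells cannot be
stratified and raises an error naming the class.

## The discriminant reduction

LDA maximises between-class over within-class scatter; only `k - 1`
directions are informative, and using all of them is the default (the
dimension sweep in this package lets users verify on their own data that
accuracy grows with the reduction dimension up to `k - 1`).

Two numerical points matter in the single-cell regime:

* **Singularity.** With more genes than cells the within-class scatter
  `S_w` is singular. We shrink it towards a scaled identity,
  `S_w^reg = (1 - γ) S_w + γ (tr S_w / p) I` with `γ = 0.01` by
  default, raising `γ` geometrically until the Cholesky factorisation
  succeeds. The eigenproblem is solved in the whitened (symmetric)
  form, and directions are unit-normalised with a deterministic sign
  convention (largest-magnitude coefficient positive) so fits are
  reproducible.
* **Positivity shift.** The downstream token embedding treats each
  coordinate as a magnitude, so the projected training matrix is
  shifted by `max(0, -min) + 1`, stored in the projection and reused
  unchanged at prediction time. Test cells can land slightly below the
  training minimum; such entries are clipped at a configurable floor of
  `10^-6` with a warning. The clip affects isolated entries at the
  extreme of the projected range and leaves predictions for
  well-separated data unchanged.

The reduction is fit on the **training part only** of each split. The
package deliberately retains the leaky alternative — fitting the
reduction on all data before splitting — inside
`lda_position_experiment()`, because quantifying that leakage is one of
the analyses the pipeline supports: the leaky order lets test labels
shape the projection and inflates measured test accuracy, drastically so
when genes are plentiful relative to cells.

## The classifier

*Tokenisation.* How a `(k-1)`-vector becomes a token sequence is a
design choice. We use the minimal standard construction for tabular
transformers: token `t` is `x_t * direction_t + bias_t` with learned
per-position vectors, plus the sinusoidal positional encoding
(even dimensions `sin(pos / 10000^(2i/d_model))`, odd dimensions the
cosine). Each coordinate is one token, so sequence length equals the
reduction dimension.

*Attention.* `softmax(Q K' / sqrt(d_k)) V` per head, with
`d_k = d_v = d_model / h`; head outputs are concatenated along the
width and mixed by an output projection. Five heads and `d_model = 40`
are the defaults. Residual connections and layer normalisation wrap
every sublayer; they are not part of the method's equations but deeper
variants do not train without them, so they are on by default and
switchable (`residual_norm = FALSE`).

*Decoder.* The optional "decoder" is a single learned query token that
cross-attends to the encoder output through one decoder layer and is
prepended as a summary token. A classification task has no target
sequence, so this is the smallest construction that gives the decoder a
defined role; it is isolated behind `use_decoder` so alternatives can
be swapped in, and the head/decoder sweep measures its effect.

*Convolution and head.* A 1-D convolution along the token axis
(16 filters, width 3, zero same-length padding, ReLU) extracts local
patterns across neighbouring discriminant coordinates; the flattened
features feed a dense softmax layer. When the token sequence is shorter
than the kernel (reductions to one or two dimensions), configurations
built from override lists shrink the kernel to the largest odd width
that fits and say so; the strict `model_config()` constructor still
rejects the combination.

*Training.* Mean cross-entropy, Adam (`lr = 10^-3`, batch 128, at most
100 epochs), early stopping when the training loss fails to improve by
`10^-5` for 10 consecutive epochs. Ties in the predicted
probability vector break towards the lowest class index. The loss used
for optimisation is computed from logits via log-sum-exp, so gradients
are exact even for saturated probabilities; the user-facing
`cross_entropy_loss()` clamps zero probabilities at a configurable
epsilon with a warning instead.

All gradients are analytic and are pinned against central finite
differences in the test suite; the batched training path is separately
tested to agree with a composition of the single-sequence reference
primitives to 10 decimal places.

## Evaluation

Five metrics are computed from the confusion matrix: accuracy
(trace over total), macro precision and macro recall (unweighted
per-class means, with a zero contribution and a warning for a class
absent from predictions or truth), macro F1 defined as the harmonic
mean of the macro precision and macro recall (not the mean of
per-class F1 — the two differ), and the Matthews correlation
coefficient in its multiclass generalisation, which reduces exactly to
the familiar binary `(TP·TN - FP·FN)/sqrt(...)` form at `k = 2`.

`repeat_evaluate()` runs the whole split/reduce/train/test cycle
`n_repeats = 5` times with seeds `base_seed + r` and reports per-repeat
values, their means and the summed confusion matrix. The sweeps
(`head_sweep()`, `dimension_sweep()`, `lda_position_experiment()`) are
thin loops over this protocol.

## The synthetic generator

`synthetic_spec()` / `simulate_cells()` emulate a labeled count matrix
with class-dependent mean structure: each class elevates its own block
of marker genes by a log-fold effect above a common base mean, counts
are negative-binomial (overdispersed, as UMI data are), and entries are
independently zeroed to mimic dropout. A rounded-Gaussian mode exists
for fast unit tests.

The defaults are the study conditions used by the tests and the
acceptance script: 4 balanced types, 2,000 cells, 500 genes, 10 markers
per type, effect size 3 (about a 20-fold marker elevation — strong,
deliberately recoverable), base mean 1, dispersion 2, dropout 0.2.
These are desk-scale stand-ins for real atlases: large enough that the
8:2 protocol and the repeat averaging behave as in practice, small
enough that the whole pipeline runs in minutes on one core. Sweep and
ablation tests use smaller instances (150–600 cells, 60–300 genes) and
correspondingly smaller architectures.

What passing on this generator shows: the pipeline recovers known
class structure end to end, the metrics are computed correctly, the
leakage and dimension effects point the right way, and everything is
reproducible from a seed. What it does not show: performance under
batch effects, library-size heterogeneity, lineage continua, imbalanced
rare types, or any other property of real tissue atlases the generator
deliberately omits. Claims about real data require real data.

## Known limitations

* Dense in-memory matrices; MTX input is densified on read. Atlases of
  several hundred thousand cells would need a chunked path.
* Training is single-threaded R; the architecture is small by design
  (sequence length `k - 1`), so this is minutes, not hours, at the
  scales above.
* The decoder wiring and tokenisation are one reasonable reading of an
  under-specified design; both sit behind config flags precisely so
  they can be replaced.
* `harmonize_pair()` matches duplicated cells by identifier only;
  duplicated content under different barcodes is not detected.
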