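# ldaformer

Supervised cell-type annotation for single-cell RNA-seq expression
matrices, combining a supervised linear discriminant embedding with a
small Transformer classifier.

## The problem

Annotating each cell in an scRNA-seq experiment with a type label (T
cell, monocyte, beta cell, ...) is the first analysis step after
quantification. Reference-free clustering needs manual marker curation;
supervised annotation instead learns the mapping from expression profile
to type on a labeled reference and transfers it to new cells. The
difficulty is dimensionality: tens of thousands of genes against a few
thousand labeled cells, with heavy technical noise and dropout.

## The model

Cells are first projected into the space that best separates the known
classes. For `k` cell types, linear discriminant analysis (LDA) finds
the directions `w` maximising the generalised Rayleigh quotient

    J(w) = (w' S_b w) / (w' S_w w)

of between-class scatter `S_b` to within-class scatter `S_w`; at most
`k - 1` directions carry class information, so each cell becomes a
`(k - 1)`-vector. Because genes far outnumber cells, `S_w` is shrunk
towards a scaled identity, `S_w^reg = (1 - γ) S_w + γ (tr S_w / p) I`,
before the eigenproblem is solved. The projected matrix is shifted by a
stored constant so every training entry is strictly positive.

Each discriminant coordinate is then lifted to a `d_model`-dimensional
token (learned per-position linear map plus sinusoidal positional
encoding) and the token sequence is processed by a Transformer encoder:
multi-head scaled dot-product attention,

    Attention(Q, K, V) = softmax(Q K' / sqrt(d_k)) V,

with `h = 5` heads by default (`d_k = d_v = d_model / h`), a
position-wise feed-forward network `max(0, x W1 + b1) W2 + b2`, and
residual connections with layer normalisation. Optionally a single
learned query cross-attends to the encoder output through one decoder
layer and is prepended as a summary token. A 1-D convolution along the
token axis extracts local features, and a linear softmax head produces
class probabilities, trained by minimising the mean cross-entropy
`-(1/n) Σ log p(y_i)` with Adam.

Performance is reported with five metrics: accuracy, macro precision,
macro recall, macro F1 (the harmonic mean of macro precision and macro
recall), and the multiclass Matthews correlation coefficient. The
standard protocol is an 8:2 stratified split repeated five times with
the mean reported.

The package also ships the surrounding protocol: gene-symbol cleaning,
per-cell log-normalisation (`log(1 + 10^4 x / total)`), removal of cell
types under 5‰ of cells, cross-dataset harmonisation, sensitivity
sweeps over attention heads / decoder use / reduction dimension, a
fit-before-split leakage experiment, and a negative-binomial synthetic
data generator so everything is testable without downloads.

## Worked example

```r
library(ldaformer)

sim <- simulate_cells(synthetic_spec(n_genes = 200, n_cells = 600, k = 3,
                                     n_marker_genes = 8, seed = 42))
sp  <- split_train_test(sim, train_fraction = 0.8, seed = 42)
fit <- ldaformer(sp$train, model = list(d_model = 20, n_heads = 2),
                 train = list(epochs = 40, batch_size = 64,
                              learning_rate = 3e-3), seed = 42)
fit
#> Discriminant-Transformer cell-type classifier
#>   200 genes -> 2 discriminant dims -> 3 classes
#>   trained on 480 cells, 38 epoch(s), final loss 0.00864

pred   <- predict(fit, sp$test$matrix)
report <- compute_metrics(sp$test$labels, match(pred, fit$classes),
                          k = 3, class_names = fit$classes)
report
#> eval_report: 120 cells, 3 classes
#>        accuracy        macro_f1 macro_precision    macro_recall             mcc
#>          0.9500          0.9520          0.9540          0.9500          0.9268
report$confusion
#>        predicted
#> true    type1 type2 type3
#>   type1    40     0     0
#>   type2     4    36     0
#>   type3     1     1    38
```

The fitted object holds the LDA projection (here 2 discriminant
dimensions for 3 classes), the network weights and the training history;
`predict()` log-normalises raw counts automatically and returns type
labels or the full probability matrix. The confusion matrix shows 6 of
120 held-out cells misassigned, mostly type2 cells drifting into the
type1 region — the pattern expected when two classes share part of
their marker signal through dropout.

A command-line front end with `simulate`, `train`, `predict` and
`sweep` subcommands is installed under
`system.file("cli", "ldaformer", package = "ldaformer")`.

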