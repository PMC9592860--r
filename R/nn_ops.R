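# Single-sequence network primitives. These are the reference definitions
# of each architectural block, written for clarity on one cell at a time;
# the training loop uses the batched path in nn_batch.R, which is tested
# for exact agreement with a composition of these functions.

#' Numerically stable row-wise softmax
#'
#' @param x Numeric matrix (or vector, treated as one row).
#' @return Matrix of the same shape whose rows are positive and sum to 1.
#' @export
softmax_rows <- function(x) {
  if (is.vector(x)) x <- matrix(x, nrow = 1)
  m <- apply(x, 1, max)
  e <- exp(x - m)
  e / rowSums(e)
}

#' Sinusoidal positional encoding
#'
#' Position `pos` (0-based) is encoded with
#' `sin(pos / 10000^(2i/d_model))` in even dimensions `2i` and
#' `cos(pos / 10000^(2i/d_model))` in odd dimensions `2i + 1`
#' (0-based dimension numbering).
#'
#' @param pos Non-negative integer position, 0-based.
#' @param d_model Encoding width.
#' @return Numeric vector of length `d_model`, entries in `[-1, 1]`.
#' @export
positional_encoding <- function(pos, d_model) {
  stopifnot(pos >= 0, d_model >= 1)
  dims <- seq_len(d_model) - 1L               # 0-based dimension index
  i2 <- dims - dims %% 2L                      # 2i for the pair the dim sits in
  angle <- pos / 10000^(i2 / d_model)
  ifelse(dims %% 2L == 0L, sin(angle), cos(angle))
}

# full L x d_model encoding table for positions 0..L-1
pe_matrix <- function(L, d_model)
  do.call(rbind, lapply(seq_len(L) - 1L, positional_encoding,
                        d_model = d_model))

#' Embed a discriminant feature vector as a token sequence
#'
#' Each of the `d` scalar coordinates becomes one token via a per-position
#' learned linear lift (`scalar * direction + bias`), after which the
#' sinusoidal positional encoding is added.
#'
#' @param features Numeric vector of length `config$n_features`.
#' @param params Model parameters ([init_model_params()]).
#' @param config A [model_config()].
#' @return Token matrix, `n_features x d_model`.
#' @export
embed_tokens <- function(features, params, config) {
  if (length(features) != config$n_features)
    stop("expected ", config$n_features, " features, got ", length(features))
  features * params$emb$dir + params$emb$bias +
    pe_matrix(config$n_features, config$d_model)
}

#' Scaled dot-product attention
#'
#' `softmax(Q K' / sqrt(d_k)) V`, softmax taken row-wise so every
#' attention row is a probability distribution over the keys.
#'
#' @param Q Query matrix `Lq x d_k`.
#' @param K Key matrix `Lk x d_k`.
#' @param V Value matrix `Lk x d_v`.
#' @return Output matrix `Lq x d_v`; the attention map is attached as
#'   attribute `"weights"`.
#' @export
scaled_dot_attention <- function(Q, K, V) {
  Q <- as.matrix(Q); K <- as.matrix(K); V <- as.matrix(V)
  if (ncol(Q) != ncol(K))
    stop("Q and K widths differ (", ncol(Q), " vs ", ncol(K), ")")
  if (nrow(K) != nrow(V))
    stop("K and V row counts differ (", nrow(K), " vs ", nrow(V), ")")
  A <- softmax_rows(Q %*% t(K) / sqrt(ncol(K)))
  structure(A %*% V, weights = A)
}

#' Multi-head attention sublayer
#'
#' Projects queries, keys and values with learned `d_model x d_model`
#' matrices, runs `n_heads` scaled dot-product attentions on the width
#' slices, concatenates the head outputs along the width and mixes them
#' with the output projection. Returns the raw sublayer output; the
#' enclosing encoder layer adds the residual connection and layer
#' normalisation.
#'
#' @param X Token sequence `L x d_model` (queries, keys and values).
#' @param params List with `Wq`, `Wk`, `Wv`, `Wo`, each
#'   `d_model x d_model`.
#' @param n_heads Head count; must divide `d_model`.
#' @return Sequence of the same shape as `X`.
#' @export
multi_head_attention <- function(X, params, n_heads)
  multi_head_cross_attention(X, X, params, n_heads)

#' @rdname multi_head_attention
#' @param Xq Query-side sequence (may differ from the key/value side, as in
#'   the decoder's cross-attention).
#' @param Xkv Key/value-side sequence.
#' @export
multi_head_cross_attention <- function(Xq, Xkv, params, n_heads) {
  dm <- ncol(Xq)
  if (dm %% n_heads != 0) stop("d_model must be divisible by n_heads")
  dk <- dm %/% n_heads
  Q <- Xq %*% params$Wq; K <- Xkv %*% params$Wk; V <- Xkv %*% params$Wv
  out <- matrix(0, nrow(Xq), dm)
  for (h in seq_len(n_heads)) {
    cols <- ((h - 1L) * dk + 1L):(h * dk)
    out[, cols] <- scaled_dot_attention(Q[, cols, drop = FALSE],
                                        K[, cols, drop = FALSE],
                                        V[, cols, drop = FALSE])
  }
  out %*% params$Wo
}

#' Position-wise feed-forward sublayer
#'
#' `max(0, X W1 + b1) W2 + b2`: two dense layers applied identically at
#' every token position, ReLU inner activation, linear outer layer, equal
#' input and output width. Returns the raw sublayer output (pre-residual).
#'
#' @param X Token sequence `L x d_model`.
#' @param params List with `W1`, `b1`, `W2`, `b2`.
#' @return Sequence of the same shape as `X`.
#' @export
feed_forward <- function(X, params) {
  H <- sweep(X %*% params$W1, 2, params$b1, "+")
  H[H < 0] <- 0
  sweep(H %*% params$W2, 2, params$b2, "+")
}

#' Row-wise layer normalisation
#'
#' @param X Matrix; each row is standardised to zero mean and unit
#'   variance, then scaled by `g` and shifted by `b`.
#' @param g,b Gain and bias vectors of length `ncol(X)`.
#' @param eps Variance floor.
#' @return Normalised matrix.
#' @export
layer_norm <- function(X, g, b, eps = 1e-5) {
  mu <- rowMeans(X)
  Xc <- X - mu
  sd_ <- sqrt(rowMeans(Xc^2) + eps)
  sweep(sweep(Xc / sd_, 2, g, "*"), 2, b, "+")
}

# one encoder layer: attention sublayer then FFN sublayer, each wrapped in
# residual + layer norm when cfg$residual_norm
encoder_layer <- function(X, layer, cfg) {
  A <- multi_head_attention(X, layer$attn, cfg$n_heads)
  X <- if (cfg$residual_norm)
    layer_norm(X + A, layer$ln1$g, layer$ln1$b) else A
  F_ <- feed_forward(X, layer$ffn)
  if (cfg$residual_norm)
    layer_norm(X + F_, layer$ln2$g, layer$ln2$b) else F_
}

#' Encode one cell as a Transformer token sequence
#'
#' Embeds the discriminant features, runs them through the encoder stack,
#' and — when the decoder is enabled — lets a single learned query
#' cross-attend to the encoder output through one decoder layer, prepending
#' the resulting summary token to the sequence.
#'
#' @param features Numeric vector of length `config$n_features`.
#' @param params Model parameters.
#' @param config A [model_config()].
#' @return Token sequence, `(n_features + use_decoder) x d_model`.
#' @export
transformer_encode <- function(features, params, config) {
  X <- embed_tokens(features, params, config)
  for (layer in params$enc) X <- encoder_layer(X, layer, config)
  if (config$use_decoder) {
    q <- params$dec$query
    A <- multi_head_cross_attention(q, X, params$dec$attn, config$n_heads)
    s <- if (config$residual_norm)
      layer_norm(q + A, params$dec$ln1$g, params$dec$ln1$b) else A
    F_ <- feed_forward(s, params$dec$ffn)
    s <- if (config$residual_norm)
      layer_norm(s + F_, params$dec$ln2$g, params$dec$ln2$b) else F_
    X <- rbind(s, X)
  }
  X
}

#' 1-D convolutional feature extraction
#'
#' Convolves the token sequence along the token axis with
#' `conv_channels` filters of width `conv_kernel` (zero same-length
#' padding, every embedding dimension treated as an input channel),
#' applies ReLU, and flattens token-major.
#'
#' @param tokens Token sequence `L x d_model`.
#' @param params List with `W` (`conv_kernel*d_model x conv_channels`) and
#'   `b` (`conv_channels`).
#' @param config A [model_config()].
#' @return Numeric vector of length `L * conv_channels`.
#' @export
conv_extract <- function(tokens, params, config) {
  L <- nrow(tokens)
  if (L < 1) stop("empty token sequence")
  k <- config$conv_kernel
  if (k > L) stop("conv_kernel (", k, ") exceeds sequence length (", L, ")")
  half <- (k - 1L) %/% 2L
  padded <- rbind(matrix(0, half, ncol(tokens)), tokens,
                  matrix(0, half, ncol(tokens)))
  cols <- lapply(seq_len(k), function(o)
    padded[o:(o + L - 1L), , drop = FALSE])
  im2col <- do.call(cbind, cols)
  out <- sweep(im2col %*% params$W, 2, params$b, "+")
  out[out < 0] <- 0
  as.vector(t(out))
}

#' Linear softmax classifier head
#'
#' @param features Flat feature vector from [conv_extract()].
#' @param params List with `W` (`length(features) x n_classes`) and `b`.
#' @return Probability vector over classes (positive, sums to 1).
#' @export
classify <- function(features, params) {
  z <- as.vector(features %*% params$W) + params$b
  as.vector(softmax_rows(z))
}

#' Mean cross-entropy loss
#'
#' Mean over cells of minus the log probability the model assigned to the
#' true class. Zero probabilities at a true label are clamped at `eps`
#' with a warning.
#'
#' @param predicted Matrix of per-cell class probabilities (rows sum to 1),
#'   or a single probability vector.
#' @param labels Integer true-class indices in `1..n_classes`.
#' @param eps Clamp for zero probabilities, default `1e-12`.
#' @return Non-negative scalar.
#' @export
cross_entropy_loss <- function(predicted, labels, eps = 1e-12) {
  if (is.vector(predicted)) predicted <- matrix(predicted, nrow = 1)
  labels <- as.integer(labels)
  stopifnot(nrow(predicted) == length(labels),
            all(labels >= 1L), all(labels <= ncol(predicted)))
  p <- predicted[cbind(seq_along(labels), labels)]
  if (any(p <= 0)) {
    warning("zero probability at ", sum(p <= 0),
            " true label(s); clamped at ", eps)
    p <- pmax(p, eps)
  }
  -mean(log(p))
}

#' Full forward pass for a single cell
#'
#' Reference composition of [transformer_encode()], [conv_extract()] and
#' [classify()]; dropout is never applied here.
#'
#' @inheritParams transformer_encode
#' @return Probability vector over the `n_classes` cell types.
#' @export
model_forward <- function(features, params, config)
  classify(conv_extract(transformer_encode(features, params, config),
                        params$conv, config),
           params$cls)
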