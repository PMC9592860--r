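#' Architecture configuration
#'
#' Collects every architecture hyperparameter of the classifier: the token
#' sequence length (one token per discriminant dimension), the embedding
#' width, the attention head count, encoder depth, feed-forward width, the
#' optional single-query decoder summary token, the 1-D convolution
#' specification, dropout, and the class count.
#'
#' @param n_features Sequence length `d` (number of discriminant
#'   dimensions; one token per dimension).
#' @param n_classes Number of cell types `k`.
#' @param d_model Embedding width; must be divisible by `n_heads`.
#'   Default 40.
#' @param n_heads Number of attention heads, default 5 (so
#'   `d_k = d_v = d_model / n_heads`).
#' @param n_encoder_layers Encoder depth, default 1.
#' @param ffn_hidden Inner width of the position-wise feed-forward
#'   network; default `4 * d_model`.
#' @param use_decoder Prepend a learned-query decoder summary token,
#'   default `TRUE`.
#' @param conv_channels Number of 1-D convolution filters, default 16.
#' @param conv_kernel Odd kernel width (same-length padding), default 3;
#'   must not exceed the token sequence length.
#' @param dropout Dropout rate in `[0, 1)` applied to sublayer outputs
#'   during training, default 0.1.
#' @param residual_norm Apply residual connections plus layer
#'   normalisation around each sublayer (default `TRUE`).
#' @param seed Integer seed used for weight initialisation.
#' @return A validated list of class `"model_config"`.
#' @export
model_config <- function(n_features, n_classes, d_model = 40L, n_heads = 5L,
                         n_encoder_layers = 1L, ffn_hidden = 4L * d_model,
                         use_decoder = TRUE, conv_channels = 16L,
                         conv_kernel = 3L, dropout = 0.1,
                         residual_norm = TRUE, seed = 1L) {
  cfg <- list(n_features = as.integer(n_features),
              n_classes = as.integer(n_classes),
              d_model = as.integer(d_model),
              n_heads = as.integer(n_heads),
              n_encoder_layers = as.integer(n_encoder_layers),
              ffn_hidden = as.integer(ffn_hidden),
              use_decoder = isTRUE(use_decoder),
              conv_channels = as.integer(conv_channels),
              conv_kernel = as.integer(conv_kernel),
              dropout = as.numeric(dropout),
              residual_norm = isTRUE(residual_norm),
              seed = as.integer(seed))
  validate_model_config(cfg)
  structure(cfg, class = "model_config")
}

validate_model_config <- function(cfg) {
  if (cfg$n_features < 1L) stop("n_features must be >= 1")
  if (cfg$n_classes < 2L) stop("n_classes must be >= 2")
  if (cfg$d_model %% cfg$n_heads != 0L)
    stop("d_model (", cfg$d_model, ") must be divisible by n_heads (",
         cfg$n_heads, ") so that d_k = d_v = d_model / h")
  if (cfg$conv_kernel %% 2L == 0L)
    stop("conv_kernel must be odd for well-defined same-length padding")
  seq_len_total <- cfg$n_features + as.integer(cfg$use_decoder)
  if (cfg$conv_kernel > seq_len_total)
    stop("conv_kernel (", cfg$conv_kernel,
         ") exceeds the token sequence length (", seq_len_total, ")")
  if (cfg$dropout < 0 || cfg$dropout >= 1) stop("dropout must be in [0, 1)")
  if (cfg$n_encoder_layers < 0L) stop("n_encoder_layers must be >= 0")
  invisible(cfg)
}

#' @export
print.model_config <- function(x, ...) {
  cat(sprintf(
    paste0("model_config: %d tokens -> %d classes | d_model %d, %d head(s), ",
           "%d encoder layer(s), decoder %s, conv %dx%d, dropout %.2f\n"),
    x$n_features, x$n_classes, x$d_model, x$n_heads, x$n_encoder_layers,
    if (x$use_decoder) "on" else "off", x$conv_channels, x$conv_kernel,
    x$dropout))
  invisible(x)
}

# total token count entering the convolution
seq_length <- function(cfg) cfg$n_features + as.integer(cfg$use_decoder)

glorot <- function(nr, nc) {
  lim <- sqrt(6 / (nr + nc))
  matrix(stats::runif(nr * nc, -lim, lim), nr, nc)
}

attn_block <- function(dm) list(Wq = glorot(dm, dm), Wk = glorot(dm, dm),
                                Wv = glorot(dm, dm), Wo = glorot(dm, dm))

ln_block <- function(dm) list(g = rep(1, dm), b = rep(0, dm))

ffn_block <- function(dm, dh) list(W1 = glorot(dm, dh), b1 = rep(0, dh),
                                   W2 = glorot(dh, dm), b2 = rep(0, dm))

#' Initialise model parameters
#'
#' Glorot-uniform weights, zero biases, unit layer-norm gains; reproducible
#' from `config$seed`.
#'
#' @param config A [model_config()].
#' @return Nested parameter list of class `"model_parameters"`.
#' @export
init_model_params <- function(config) {
  validate_model_config(config)
  set.seed(config$seed)
  dm <- config$d_model; L <- config$n_features
  p <- list(emb = list(dir = glorot(L, dm), bias = matrix(0, L, dm)))
  p$enc <- lapply(seq_len(config$n_encoder_layers), function(i)
    list(attn = attn_block(dm), ln1 = ln_block(dm),
         ffn = ffn_block(dm, config$ffn_hidden), ln2 = ln_block(dm)))
  if (config$use_decoder)
    p$dec <- list(query = glorot(1L, dm), attn = attn_block(dm),
                  ln1 = ln_block(dm),
                  ffn = ffn_block(dm, config$ffn_hidden), ln2 = ln_block(dm))
  Lc <- seq_length(config)
  p$conv <- list(W = glorot(config$conv_kernel * dm, config$conv_channels),
                 b = rep(0, config$conv_channels))
  p$cls <- list(W = glorot(Lc * config$conv_channels, config$n_classes),
                b = rep(0, config$n_classes))
  structure(p, class = "model_parameters")
}
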