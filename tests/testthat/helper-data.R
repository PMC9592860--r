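# Shared fixtures, built in code.

# small expression matrix with hand-set values
tiny_em <- function(values, genes = NULL, cells = NULL,
                    normalized = FALSE) {
  values <- as.matrix(values)
  if (is.null(genes)) genes <- sprintf("g%d", seq_len(nrow(values)))
  if (is.null(cells)) cells <- sprintf("c%d", seq_len(ncol(values)))
  expression_matrix(values, genes, cells, normalized = normalized)
}

# well-separated Gaussian-mode synthetic dataset for fast tests
tiny_sim <- function(n_cells = 200, k = 3, n_genes = 60, effect = 3,
                     seed = 1, ...) {
  simulate_cells(synthetic_spec(n_genes = n_genes, n_cells = n_cells,
                                k = k, n_marker_genes = 5,
                                effect_size = effect, base_mean = 1,
                                dropout_rate = 0.1, seed = seed,
                                mode = "gaussian", ...))
}

# small architecture / short training for unit tests
fast_model <- function(...)
  utils::modifyList(list(d_model = 16L, n_heads = 2L, ffn_hidden = 32L,
                         conv_channels = 4L, dropout = 0), list(...))

fast_train <- function(...)
  utils::modifyList(list(epochs = 30L, batch_size = 32L,
                         learning_rate = 3e-3, patience = 8L), list(...))

# independent per-cell tally of the five metrics, written as plain loops
# so it shares no code with compute_metrics()
oracle_metrics <- function(true, pred, k) {
  tp <- fp <- fn <- tn <- numeric(k)
  for (c in seq_len(k)) {
    for (i in seq_along(true)) {
      is_t <- true[i] == c
      is_p <- pred[i] == c
      if (is_t && is_p) tp[c] <- tp[c] + 1
      if (!is_t && is_p) fp[c] <- fp[c] + 1
      if (is_t && !is_p) fn[c] <- fn[c] + 1
      if (!is_t && !is_p) tn[c] <- tn[c] + 1
    }
  }
  prec <- ifelse(tp + fp > 0, tp / (tp + fp), 0)
  rec <- ifelse(tp + fn > 0, tp / (tp + fn), 0)
  P <- mean(prec); R <- mean(rec)
  # MCC as the Pearson correlation between one-hot label indicators
  X <- matrix(0, length(true), k); X[cbind(seq_along(true), true)] <- 1
  Y <- matrix(0, length(pred), k); Y[cbind(seq_along(pred), pred)] <- 1
  Xc <- sweep(X, 2, colMeans(X)); Yc <- sweep(Y, 2, colMeans(Y))
  num <- sum(Xc * Yc)
  den <- sqrt(sum(Xc * Xc)) * sqrt(sum(Yc * Yc))
  list(accuracy = mean(true == pred),
       macro_precision = P, macro_recall = R,
       macro_f1 = if (P + R > 0) 2 * P * R / (P + R) else 0,
       mcc = if (den > 0) num / den else 0)
}

# random parameters drawn independently of init_model_params
random_params <- function(cfg, seed) {
  set.seed(seed)
  p <- init_model_params(cfg)
  jiggle <- function(x)
    if (is.list(x)) lapply(x, jiggle) else
      x + stats::rnorm(length(x), sd = 0.3)
  structure(jiggle(p), class = "model_parameters")
}
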