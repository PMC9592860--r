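# Repeat-averaged evaluation protocol and the sensitivity sweeps.

ensure_normalized <- function(data, scale_factor = 1e4) {
  if (data$matrix$normalized) return(data)
  labeled_dataset(log_normalize(data$matrix, scale_factor), data$labels,
                  data$class_names)
}

# one split -> fit -> test cycle; a pre-fitted projection (fit on the full
# dataset) may be injected to reproduce the leaky fit-before-split order
eval_one_split <- function(split, d, model, train, seed, proj = NULL) {
  tr <- split$train; te <- split$test
  if (is.null(proj)) proj <- fit_lda(tr, d = d)
  feats_tr <- predict(proj, tr$matrix)
  feats_te <- predict(proj, te$matrix)
  mcfg <- as_model_config(model, n_features = proj$d,
                          n_classes = length(tr$class_names), seed = seed)
  tcfg <- as_train_config(train)
  fitted <- train_network(feats_tr, tr$labels, mcfg, tcfg, seed = seed)
  probs <- predict_network(fitted$params, feats_te, mcfg)
  pred <- apply(probs, 1, which.max)
  compute_metrics(te$labels, pred, k = length(tr$class_names),
                  class_names = tr$class_names)
}

#' Repeat-averaged evaluation
#'
#' Runs `n_repeats` independent split / fit-LDA / train / test cycles
#' (repeat `r` seeded with `base_seed + r`) and reports the mean of each
#' metric together with the per-repeat values and the summed confusion
#' matrix.
#'
#' @param data A [labeled_dataset()] (raw counts are log-normalised once
#'   up front).
#' @param d Discriminant dimension, default `k - 1`.
#' @param model,train Configuration overrides, as in [ldaformer()].
#'   `train$n_repeats` and `train$base_seed` control the protocol.
#' @param train_fraction Training fraction of each split, default 0.8.
#' @param proj Optional pre-fitted [fit_lda()] projection; when given it is
#'   reused for every repeat instead of being refit on each training part
#'   (the label-leaking order studied by [lda_position_experiment()]).
#' @return An `"eval_report"` whose metric fields are means over repeats,
#'   with `per_repeat` holding the individual values.
#' @export
repeat_evaluate <- function(data, d = NULL, model = list(), train = list(),
                            train_fraction = 0.8, proj = NULL) {
  data <- ensure_normalized(data)
  tcfg <- as_train_config(train)
  reps <- vector("list", tcfg$n_repeats)
  for (r in seq_len(tcfg$n_repeats)) {
    seed_r <- tcfg$base_seed + r
    split <- split_train_test(data, train_fraction, seed = seed_r)
    reps[[r]] <- eval_one_split(split, d, model, train, seed_r, proj = proj)
  }
  per <- data.frame(repeat_ = seq_len(tcfg$n_repeats),
                    seed = tcfg$base_seed + seq_len(tcfg$n_repeats))
  for (m in metric_names)
    per[[m]] <- vapply(reps, function(r) r[[m]], numeric(1))
  out <- reps[[1]]
  out$confusion <- Reduce(`+`, lapply(reps, `[[`, "confusion"))
  rs <- rowSums(out$confusion)
  out$percent <- out$confusion * 0
  out$percent[rs > 0, ] <- 100 * out$confusion[rs > 0, , drop = FALSE] /
    rs[rs > 0]
  for (m in metric_names) out[[m]] <- mean(per[[m]])
  out$n <- sum(out$confusion)
  out$n_repeats <- tcfg$n_repeats
  out$per_repeat <- per
  out
}

sweep_row <- function(report) {
  vals <- lapply(metric_names, function(m) report[[m]])
  names(vals) <- metric_names
  as.data.frame(vals)
}

#' Attention-head / decoder sensitivity sweep
#'
#' Evaluates every combination of attention-head count and decoder flag
#' with [repeat_evaluate()]. Head counts that do not divide the requested
#' embedding width get the width rounded up to the next multiple (logged
#' with a message).
#'
#' @inheritParams repeat_evaluate
#' @param heads Integer vector of head counts (the reference protocol uses
#'   `1:10`).
#' @param decoder_variants Logical vector of decoder settings, default
#'   `c(TRUE, FALSE)`.
#' @return A data frame with one row per (head, decoder) combination and
#'   the five metric columns; the full reports are attached as attribute
#'   `"reports"`.
#' @export
head_sweep <- function(data, heads, decoder_variants = c(TRUE, FALSE),
                       d = NULL, model = list(), train = list(),
                       train_fraction = 0.8) {
  data <- ensure_normalized(data)
  base_dm <- if (!is.null(model$d_model)) model$d_model else 40L
  rows <- list(); reports <- list()
  for (h in heads) for (dec in decoder_variants) {
    dm <- as.integer(ceiling(base_dm / h) * h)
    if (dm != base_dm)
      message("d_model adjusted ", base_dm, " -> ", dm,
              " to be divisible by ", h, " head(s)")
    mod <- utils::modifyList(model, list(n_heads = as.integer(h),
                                         d_model = dm, use_decoder = dec))
    rep_ <- repeat_evaluate(data, d = d, model = mod, train = train,
                            train_fraction = train_fraction)
    rows[[length(rows) + 1L]] <-
      cbind(data.frame(heads = h, decoder = dec), sweep_row(rep_))
    reports[[length(reports) + 1L]] <- rep_
  }
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  attr(out, "reports") <- reports
  out
}

#' Reduction-dimension sensitivity sweep
#'
#' @inheritParams repeat_evaluate
#' @param dims Integer vector of discriminant dimensions, each in
#'   `1..k-1`.
#' @return A data frame with one row per dimension; full reports attached
#'   as attribute `"reports"`.
#' @export
dimension_sweep <- function(data, dims, model = list(), train = list(),
                            train_fraction = 0.8) {
  data <- ensure_normalized(data)
  k <- length(data$class_names)
  dims <- as.integer(dims)
  if (any(dims < 1L | dims > k - 1L))
    stop("dims must lie in 1..k-1 (k = ", k, ")")
  rows <- list(); reports <- list()
  for (dd in dims) {
    rep_ <- repeat_evaluate(data, d = dd, model = model, train = train,
                            train_fraction = train_fraction)
    rows[[length(rows) + 1L]] <- cbind(data.frame(dim = dd),
                                       sweep_row(rep_))
    reports[[length(reports) + 1L]] <- rep_
  }
  out <- if (length(rows))
    do.call(rbind, c(rows, list(make.row.names = FALSE)))
  else
    data.frame(dim = integer(0))
  attr(out, "reports") <- reports
  out
}

#' Fit-before-split versus fit-after-split comparison
#'
#' Runs the evaluation protocol twice with identical seeds (hence
#' identical splits): once fitting the discriminant reduction on the
#' training part of each split only (the honest order) and once fitting it
#' on the full dataset before splitting. The second order lets test-cell
#' labels inform the reduction, so its measured test accuracy is inflated;
#' it is reported purely to quantify that leakage.
#'
#' @inheritParams repeat_evaluate
#' @return A list of class `"lda_position_experiment"` with elements
#'   `honest` and `leaky`, both `"eval_report"` objects.
#' @export
lda_position_experiment <- function(data, d = NULL, model = list(),
                                    train = list(), train_fraction = 0.8) {
  data <- ensure_normalized(data)
  honest <- repeat_evaluate(data, d = d, model = model, train = train,
                            train_fraction = train_fraction)
  full_proj <- fit_lda(data, d = d)
  leaky <- repeat_evaluate(data, d = d, model = model, train = train,
                           train_fraction = train_fraction,
                           proj = full_proj)
  structure(list(honest = honest, leaky = leaky),
            class = "lda_position_experiment")
}

#' @export
print.lda_position_experiment <- function(x, ...) {
  cat("LDA placement experiment\n")
  cat("-- honest (reduction fit on training part only):\n")
  print(x$honest)
  cat("-- LEAKY (reduction fit on the full dataset before splitting;\n")
  cat("   test metrics are inflated by label leakage):\n")
  print(x$leaky)
  invisible(x)
}

#' Optional 2-D embedding export for visualisation
#'
#' Projects cells to the fitted discriminant space and returns the first
#' two coordinates (or a classical multidimensional scaling to 2-D when
#' `d > 2`), for quick scatter plots of the learned separation. Purely a
#' visual aid.
#'
#' @param proj An `"lda_projection"`.
#' @param matrix An [expression_matrix()].
#' @return Data frame with columns `cell_id`, `dim1`, `dim2`.
#' @export
embedding_2d <- function(proj, matrix) {
  feats <- predict(proj, matrix)
  if (ncol(feats) > 2) {
    xy <- stats::cmdscale(stats::dist(feats), k = 2)
  } else if (ncol(feats) == 2) {
    xy <- feats
  } else {
    xy <- cbind(feats[, 1], 0)
  }
  data.frame(cell_id = matrix$cell_ids, dim1 = xy[, 1], dim2 = xy[, 2])
}
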