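#' Training configuration
#'
#' @param epochs Maximum training epochs, default 100.
#' @param batch_size Mini-batch size, default 128.
#' @param learning_rate Step size, default `1e-3`.
#' @param optimizer `"adam"` (default) or plain `"sgd"`.
#' @param patience Early-stopping patience: training stops after this many
#'   epochs without the train loss improving by at least `min_delta`.
#' @param min_delta Minimum loss improvement that resets the patience
#'   counter, default `1e-5`.
#' @param n_repeats Number of independent split/train/test repeats used by
#'   [repeat_evaluate()], default 5.
#' @param base_seed Base seed for the repeat protocol; repeat `r` uses
#'   `base_seed + r`.
#' @return A list of class `"train_config"`.
#' @export
train_config <- function(epochs = 100L, batch_size = 128L,
                         learning_rate = 1e-3,
                         optimizer = c("adam", "sgd"), patience = 10L,
                         min_delta = 1e-5, n_repeats = 5L,
                         base_seed = 1L) {
  optimizer <- match.arg(optimizer)
  if (epochs < 1) stop("epochs must be >= 1")
  if (n_repeats < 1) stop("n_repeats must be >= 1")
  if (batch_size < 1) stop("batch_size must be >= 1")
  if (learning_rate < 0) stop("learning_rate must be >= 0")
  structure(list(epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, optimizer = optimizer,
                 patience = as.integer(patience), min_delta = min_delta,
                 n_repeats = as.integer(n_repeats),
                 base_seed = as.integer(base_seed)),
            class = "train_config")
}

as_model_config <- function(model, n_features, n_classes, seed) {
  if (inherits(model, "model_config")) return(model)
  stopifnot(is.list(model))
  args <- c(list(n_features = n_features, n_classes = n_classes), model)
  if (is.null(args$seed)) args$seed <- seed
  # short sequences (small d) cannot carry the default kernel width; shrink
  # it to the largest odd width that fits
  use_dec <- if (is.null(args$use_decoder)) TRUE else isTRUE(args$use_decoder)
  seqlen <- as.integer(n_features) + as.integer(use_dec)
  kern <- if (is.null(args$conv_kernel)) 3L else as.integer(args$conv_kernel)
  if (kern > seqlen) {
    newk <- if (seqlen %% 2L == 1L) seqlen else seqlen - 1L
    message("conv_kernel reduced ", kern, " -> ", newk,
            " to fit the token sequence length ", seqlen)
    args$conv_kernel <- newk
  }
  do.call(model_config, args)
}

as_train_config <- function(train) {
  if (inherits(train, "train_config")) return(train)
  stopifnot(is.list(train))
  do.call(train_config, train)
}

#' Fit a discriminant-Transformer cell-type classifier
#'
#' The main fitting function. The labeled training data is log-normalised
#' (unless it already is), reduced to `d` discriminant dimensions by
#' shrinkage-regularised LDA with a stored positive shift ([fit_lda()]),
#' and the resulting per-cell feature vectors are classified by a
#' Transformer encoder, an optional single-query decoder summary token, a
#' 1-D convolutional extractor and a linear softmax head, trained with
#' mini-batch gradient descent on the mean cross-entropy.
#'
#' @param data A [labeled_dataset()] holding the *training* cells. Raw
#'   counts are log-normalised automatically; pass already-normalised data
#'   with its `normalized` flag set to skip that.
#' @param d Discriminant dimension; default `k - 1` for `k` cell types.
#' @param model A [model_config()], or a list of overrides for its
#'   arguments (e.g. `list(n_heads = 3, use_decoder = FALSE)`).
#' @param train A [train_config()], or a list of overrides.
#' @param seed Integer seed governing weight initialisation, batch order
#'   and dropout.
#' @param scale_factor Passed to [log_normalize()] when normalisation is
#'   needed.
#' @param verbose Print per-epoch losses.
#' @return An object of class `"ldaformer"` with elements `projection`,
#'   `parameters`, `model_config`, `train_config`, `history`, `classes`.
#' @examples
#' sim <- simulate_cells(synthetic_spec(n_genes = 60, n_cells = 150, k = 3,
#'                                      n_marker_genes = 5, seed = 7))
#' sp <- split_train_test(sim, seed = 7)
#' fit <- ldaformer(sp$train, model = list(d_model = 10, conv_channels = 4),
#'                  train = list(epochs = 3), seed = 7)
#' table(predict(fit, sp$test$matrix), sp$test$class_names[sp$test$labels])
#' @export
ldaformer <- function(data, d = NULL, model = list(), train = list(),
                      seed = 1L, scale_factor = 1e4, verbose = FALSE) {
  stopifnot(inherits(data, "labeled_dataset"))
  cl <- match.call()
  if (!data$matrix$normalized)
    data <- labeled_dataset(log_normalize(data$matrix, scale_factor),
                            data$labels, data$class_names)
  k <- length(data$class_names)
  proj <- fit_lda(data, d = d)
  feats <- predict(proj, data$matrix)
  mcfg <- as_model_config(model, n_features = proj$d, n_classes = k,
                          seed = seed)
  tcfg <- as_train_config(train)
  fitted <- train_network(feats, data$labels, mcfg, tcfg,
                          seed = as.integer(seed), verbose = verbose)
  structure(list(projection = proj, parameters = fitted$params,
                 model_config = mcfg, train_config = tcfg,
                 history = fitted$history, classes = data$class_names,
                 seed = as.integer(seed), n_train = n_cells(data$matrix),
                 call = cl),
            class = "ldaformer")
}

#' @export
print.ldaformer <- function(x, ...) {
  cat("Discriminant-Transformer cell-type classifier\n")
  cat(sprintf("  %d genes -> %d discriminant dims -> %d classes\n",
              nrow(x$projection$weights), x$projection$d,
              length(x$classes)))
  cat(sprintf("  trained on %d cells, %d epoch(s), final loss %.5f\n",
              x$n_train, nrow(x$history),
              x$history$loss[nrow(x$history)]))
  invisible(x)
}

#' @export
summary.ldaformer <- function(object, ...) {
  print(object)
  print(object$model_config)
  cat(sprintf("  classes: %s\n", paste(object$classes, collapse = ", ")))
  cat(sprintf("  LDA shift %.4f, shrinkage %.3g\n",
              object$projection$shift, object$projection$shrinkage))
  invisible(object)
}

#' Predict cell types for new cells
#'
#' @param object A fitted `"ldaformer"` model.
#' @param newdata An [expression_matrix()] (normalised the same way as the
#'   training data; raw counts are log-normalised automatically) or a
#'   [labeled_dataset()], whose matrix is used.
#' @param type `"class"` for predicted labels (ties broken towards the
#'   lowest class index), `"prob"` for the full probability matrix.
#' @param scale_factor Passed to [log_normalize()] if `newdata` is raw.
#' @param ... Unused.
#' @return Character vector of predicted types, or an
#'   `n_cells x n_classes` probability matrix whose rows sum to 1.
#' @export
predict.ldaformer <- function(object, newdata, type = c("class", "prob"),
                              scale_factor = 1e4, ...) {
  type <- match.arg(type)
  if (inherits(newdata, "labeled_dataset")) newdata <- newdata$matrix
  stopifnot(inherits(newdata, "expression_matrix"))
  if (!newdata$normalized) newdata <- log_normalize(newdata, scale_factor)
  feats <- predict(object$projection, newdata)
  probs <- predict_network(object$parameters, feats, object$model_config)
  dimnames(probs) <- list(newdata$cell_ids, object$classes)
  if (type == "prob") return(probs)
  idx <- apply(probs, 1, which.max)   # first maximum = lowest class index
  stats::setNames(object$classes[idx], newdata$cell_ids)
}

#' Predicted class indices (internal convenience)
#' @noRd
predict_indices <- function(object, newdata) {
  cls <- predict(object, newdata, type = "class")
  match(cls, object$classes)
}

#' @export
plot.ldaformer <- function(x, ...) {
  graphics::plot(x$history$epoch, x$history$loss, type = "l",
                 xlab = "epoch", ylab = "mean training cross-entropy",
                 main = "training loss", ...)
  invisible(x)
}

#' Save or load a fitted model
#'
#' The checkpoint is a single RDS archive holding a versioned schema:
#' the model configuration, the learned parameters and the fitted LDA
#' projection (weights, shift, gene list, class names).
#'
#' @param object A fitted `"ldaformer"`.
#' @param path Checkpoint path.
#' @export
save_ldaformer <- function(object, path) {
  stopifnot(inherits(object, "ldaformer"))
  obj <- unclass(object)
  obj$call <- NULL
  saveRDS(list(schema = "ldaformer-checkpoint-1", model = obj), path)
  invisible(path)
}

#' @rdname save_ldaformer
#' @export
load_ldaformer <- function(path) {
  x <- tryCatch(readRDS(path), error = function(e)
    stop("cannot read checkpoint: ", path, " (", conditionMessage(e), ")"))
  if (!is.list(x) || !identical(x$schema, "ldaformer-checkpoint-1"))
    stop("not an ldaformer checkpoint: ", path)
  structure(x$model, class = "ldaformer")
}
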