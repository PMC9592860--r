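#' Confusion matrix with row-normalised percentages
#'
#' Entry `(i, j)` counts cells of true class `i` predicted as class `j`.
#'
#' @param true_labels,predicted_labels Integer class indices in `1..k`.
#' @param k Number of classes; defaults to the largest index seen.
#' @param class_names Optional dimension names.
#' @return List with `counts` (k x k integer matrix) and `percent`
#'   (rows divided by row totals, times 100; zero rows stay zero).
#' @export
confusion_matrix <- function(true_labels, predicted_labels, k = NULL,
                             class_names = NULL) {
  true_labels <- as.integer(true_labels)
  predicted_labels <- as.integer(predicted_labels)
  if (!length(true_labels)) stop("empty label vectors")
  if (length(true_labels) != length(predicted_labels))
    stop("label vectors differ in length")
  if (is.null(k)) k <- max(true_labels, predicted_labels)
  k <- as.integer(k)
  if (any(true_labels < 1L | true_labels > k) ||
      any(predicted_labels < 1L | predicted_labels > k))
    stop("labels must lie in 1..k")
  counts <- matrix(0L, k, k)
  for (i in seq_along(true_labels))
    counts[true_labels[i], predicted_labels[i]] <-
      counts[true_labels[i], predicted_labels[i]] + 1L
  if (!is.null(class_names))
    dimnames(counts) <- list(true = class_names, predicted = class_names)
  rs <- rowSums(counts)
  percent <- counts * 0
  nz <- rs > 0
  percent[nz, ] <- 100 * counts[nz, , drop = FALSE] / rs[nz]
  list(counts = counts, percent = percent)
}

# multiclass Matthews correlation from a confusion matrix; reduces to the
# familiar binary (TP*TN - FP*FN) / sqrt(...) formula at k = 2
mcc_from_confusion <- function(C) {
  C <- as.matrix(C)
  s <- sum(C)
  c_ <- sum(diag(C))
  t_ <- rowSums(C)   # true-class totals
  p_ <- colSums(C)   # predicted-class totals
  num <- c_ * s - sum(p_ * t_)
  den <- sqrt(s^2 - sum(p_^2)) * sqrt(s^2 - sum(t_^2))
  if (den == 0) return(0)
  num / den
}

#' Classification metrics for cell-type annotation
#'
#' Computes the five evaluation metrics used throughout the package:
#' overall accuracy (trace of the confusion matrix over its total), macro
#' precision and macro recall (unweighted means of the per-class values),
#' macro F1 as the harmonic mean `2PR/(P+R)` of the *macro* precision and
#' recall, and the multiclass Matthews correlation coefficient. A class
#' with an undefined per-class term (never predicted, or absent from the
#' truth) contributes 0 to its macro average, with a warning.
#'
#' @inheritParams confusion_matrix
#' @return An object of class `"eval_report"`: the confusion matrix plus
#'   `accuracy`, `macro_precision`, `macro_recall`, `macro_f1`, `mcc`.
#' @export
compute_metrics <- function(true_labels, predicted_labels, k = NULL,
                            class_names = NULL) {
  cm <- confusion_matrix(true_labels, predicted_labels, k, class_names)
  C <- cm$counts
  k <- nrow(C)
  tp <- diag(C)
  fp <- colSums(C) - tp
  fn <- rowSums(C) - tp
  prec_den <- tp + fp
  rec_den <- tp + fn
  if (any(prec_den == 0) || any(rec_den == 0))
    warning("class(es) absent from predictions or truth contribute 0 ",
            "to the macro averages")
  prec <- ifelse(prec_den > 0, tp / prec_den, 0)
  rec <- ifelse(rec_den > 0, tp / rec_den, 0)
  macro_p <- mean(prec)
  macro_r <- mean(rec)
  f1 <- if (macro_p + macro_r > 0)
    2 * macro_p * macro_r / (macro_p + macro_r) else 0
  structure(list(confusion = C, percent = cm$percent,
                 accuracy = sum(tp) / sum(C),
                 macro_precision = macro_p, macro_recall = macro_r,
                 macro_f1 = f1, mcc = mcc_from_confusion(C),
                 n = sum(C), k = k),
            class = "eval_report")
}

metric_names <- c("accuracy", "macro_f1", "macro_precision",
                  "macro_recall", "mcc")

#' @export
print.eval_report <- function(x, digits = 4, ...) {
  cat(sprintf("eval_report: %d cells, %d classes", x$n, x$k))
  if (!is.null(x$n_repeats) && x$n_repeats > 1)
    cat(sprintf(" (mean of %d repeats)", x$n_repeats))
  cat("\n")
  vals <- vapply(metric_names, function(m) x[[m]], numeric(1))
  print(round(vals, digits))
  invisible(x)
}

#' Serialise an evaluation report as JSON
#'
#' Writes the five metrics, the confusion counts, and any per-repeat
#' values to a JSON file with stable formatting (so identical reports give
#' byte-identical files).
#'
#' @param report An `"eval_report"`.
#' @param path Output path.
#' @export
write_eval_report <- function(report, path) {
  stopifnot(inherits(report, "eval_report"))
  out <- list(
    n = report$n, k = report$k,
    metrics = lapply(stats::setNames(metric_names, metric_names),
                     function(m) report[[m]]),
    confusion = unname(apply(report$confusion, 1, as.list, simplify = FALSE)))
  if (!is.null(report$per_repeat)) out$per_repeat <- report$per_repeat
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(path)
}
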