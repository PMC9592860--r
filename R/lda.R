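#' Fit a supervised linear discriminant reduction
#'
#' Projects normalised expression profiles onto the `d` directions that
#' maximise between-class relative to within-class scatter. Because
#' single-cell data typically has many more genes than cells, the pooled
#' within-class covariance is shrunk towards a scaled identity before the
#' generalised eigenproblem is solved:
#' \deqn{S_w^{reg} = (1-\gamma) S_w + \gamma \frac{tr(S_w)}{p} I.}
#' The projected training matrix is then shifted by a stored constant so
#' every entry is strictly positive (the shift is
#' `max(0, -min(projected)) + 1`), which the downstream token embedding
#' relies on.
#'
#' @param train A normalised [labeled_dataset()] with `k >= 2` classes.
#' @param d Target dimension, at most `k - 1`; defaults to `k - 1`, the
#'   number of informative discriminant directions.
#' @param shrinkage Shrinkage weight `gamma` in `[0, 1]` for the
#'   within-class covariance; default 0.01. Automatically raised if the
#'   regularised matrix is still not positive definite.
#' @return An object of class `"lda_projection"`: `weights`
#'   (`n_genes x d`), `d`, `shift`, `fitted_gene_symbols`, `class_names`,
#'   `eigenvalues`.
#' @export
fit_lda <- function(train, d = NULL, shrinkage = 0.01) {
  stopifnot(inherits(train, "labeled_dataset"))
  if (!train$matrix$normalized)
    stop("fit_lda expects a normalised matrix; run log_normalize() first")
  k <- length(train$class_names)
  if (k < 2) stop("need at least 2 classes to fit a discriminant reduction")
  if (is.null(d)) d <- k - 1L
  d <- as.integer(d)
  if (d < 1L || d > k - 1L)
    stop("d must be in 1..k-1 (k = ", k, " classes give at most ",
         k - 1L, " informative directions)")
  X <- t(train$matrix$values)              # cells x genes
  y <- train$labels
  n <- nrow(X); p <- ncol(X)
  if (n <= k) stop("need more cells than classes to estimate scatter")
  mu <- colMeans(X)
  Sw <- matrix(0, p, p)
  Sb <- matrix(0, p, p)
  for (c in seq_len(k)) {
    Xi <- X[y == c, , drop = FALSE]
    mi <- colMeans(Xi)
    Xc <- sweep(Xi, 2, mi)
    Sw <- Sw + crossprod(Xc)
    dm <- mi - mu
    Sb <- Sb + nrow(Xi) * tcrossprod(dm)
  }
  Sw <- Sw / (n - k)
  Sb <- Sb / n
  directions <- lda_directions(Sw, Sb, d, shrinkage)
  proj <- X %*% directions$W
  shift <- max(0, -min(proj)) + 1
  structure(list(weights = directions$W, d = d, shift = shift,
                 fitted_gene_symbols = train$matrix$gene_symbols,
                 class_names = train$class_names,
                 eigenvalues = directions$values,
                 shrinkage = directions$shrinkage),
            class = "lda_projection")
}

# solve the generalised eigenproblem Sb w = lambda Sw_reg w via whitening;
# raises gamma geometrically until the Cholesky succeeds
lda_directions <- function(Sw, Sb, d, shrinkage) {
  p <- ncol(Sw)
  target <- mean(diag(Sw))
  if (target <= 0) target <- 1
  gamma <- max(shrinkage, 1e-8)
  U <- NULL
  while (is.null(U) && gamma <= 1) {
    Sreg <- (1 - gamma) * Sw + gamma * target * diag(p)
    U <- tryCatch(chol(Sreg), error = function(e) NULL)
    if (is.null(U)) gamma <- gamma * 10
  }
  if (is.null(U)) stop("within-class scatter could not be regularised")
  # M = U^{-T} Sb U^{-1}, symmetric; its top eigenvectors whiten back to W
  A <- backsolve(U, Sb, transpose = TRUE)
  M <- t(backsolve(U, t(A), transpose = TRUE))
  M <- (M + t(M)) / 2
  eig <- eigen(M, symmetric = TRUE)
  W <- backsolve(U, eig$vectors[, seq_len(d), drop = FALSE])
  # unit-norm columns with a deterministic sign convention
  for (j in seq_len(d)) {
    w <- W[, j]
    w <- w / sqrt(sum(w^2))
    i <- which.max(abs(w))
    if (w[i] < 0) w <- -w
    W[, j] <- w
  }
  list(W = W, values = eig$values[seq_len(d)], shrinkage = gamma)
}

#' @export
print.lda_projection <- function(x, ...) {
  cat(sprintf(
    "lda_projection: %d genes -> %d discriminant dimensions (k = %d), shift %.4f\n",
    nrow(x$weights), x$d, length(x$class_names), x$shift))
  invisible(x)
}

#' Project cells into the fitted discriminant space
#'
#' Applies the fitted directions to an expression matrix and adds the
#' stored positive shift, returning cells as rows. The gene list must match
#' the one the projection was fitted on (reordered by symbol if needed).
#' Training data is strictly positive by construction of the shift; rare
#' test-set entries that remain non-positive are clipped at `floor` with a
#' warning.
#'
#' @param object An `"lda_projection"` from [fit_lda()].
#' @param matrix An [expression_matrix()] (normalised the same way as the
#'   training data).
#' @param floor Positivity floor applied after the shift, default `1e-6`.
#' @param ... Unused.
#' @return Numeric matrix, `n_cells x d`, rownames the cell ids.
#' @export
predict.lda_projection <- function(object, matrix, floor = 1e-6, ...) {
  stopifnot(inherits(matrix, "expression_matrix"))
  if (!identical(matrix$gene_symbols, object$fitted_gene_symbols)) {
    idx <- match(object$fitted_gene_symbols, matrix$gene_symbols)
    if (anyNA(idx)) {
      miss <- object$fitted_gene_symbols[is.na(idx)]
      stop("matrix is missing ", length(miss), " fitted gene(s), e.g. ",
           paste(utils::head(miss, 5), collapse = ", "))
    }
    matrix <- em_subset(matrix, genes = idx)
  }
  out <- t(matrix$values) %*% object$weights + object$shift
  if (any(out <= 0)) {
    warning(sum(out <= 0), " projected entr(ies) were non-positive; ",
            "clipped at ", floor)
    out[out <= 0] <- floor
  }
  rownames(out) <- matrix$cell_ids
  colnames(out) <- paste0("LD", seq_len(object$d))
  out
}

#' @rdname predict.lda_projection
#' @export
lda_transform <- function(object, matrix, floor = 1e-6)
  predict.lda_projection(object, matrix, floor = floor)
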