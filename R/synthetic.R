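#' Specification for a synthetic labeled count matrix
#'
#' Describes a negative-binomial scRNA-seq-like generative model with
#' class-dependent mean structure: every class elevates the mean of its
#' own block of marker genes by a log-fold effect, all other (background)
#' genes share a common base mean, counts are overdispersed, and entries
#' are independently zeroed to mimic dropout. The defaults describe the
#' study conditions used throughout the package's tests: 4 balanced cell
#' types, 2,000 cells, 500 genes, 10 markers per type with a 3 log-fold
#' elevation.
#'
#' @param n_genes Number of genes, default 500.
#' @param n_cells Number of cells, default 2000.
#' @param k Number of cell types, default 4.
#' @param class_proportions Class proportions summing to 1; default equal.
#' @param n_marker_genes Markers per class, default 10; requires
#'   `k * n_marker_genes <= n_genes`.
#' @param effect_size Log-fold elevation of marker means (marker mean is
#'   `base_mean * exp(effect_size)`), default 3.
#' @param base_mean Expected count of background genes, default 1.
#' @param dispersion Negative-binomial size parameter (smaller = more
#'   overdispersed), default 2.
#' @param dropout_rate Probability an entry is zeroed, default 0.2.
#' @param seed Integer seed.
#' @param mode `"nb"` for negative-binomial counts (default) or
#'   `"gaussian"` for a fast rounded-Gaussian approximation used in quick
#'   unit tests.
#' @return A validated list of class `"synthetic_spec"`.
#' @export
synthetic_spec <- function(n_genes = 500L, n_cells = 2000L, k = 4L,
                           class_proportions = NULL, n_marker_genes = 10L,
                           effect_size = 3, base_mean = 1, dispersion = 2,
                           dropout_rate = 0.2, seed = 1L,
                           mode = c("nb", "gaussian")) {
  mode <- match.arg(mode)
  if (is.null(class_proportions)) class_proportions <- rep(1 / k, k)
  if (length(class_proportions) != k)
    stop("class_proportions must have length k = ", k)
  if (abs(sum(class_proportions) - 1) > 1e-9)
    stop("class_proportions must sum to 1")
  if (any(class_proportions <= 0)) stop("class_proportions must be positive")
  if (k < 2) stop("k must be >= 2")
  if (n_marker_genes < 1) stop("n_marker_genes must be >= 1")
  if (k * n_marker_genes > n_genes)
    stop("k * n_marker_genes (", k * n_marker_genes,
         ") exceeds n_genes (", n_genes, ")")
  if (base_mean <= 0 || dispersion <= 0)
    stop("base_mean and dispersion must be positive")
  if (effect_size < 0) stop("effect_size must be >= 0")
  if (dropout_rate < 0 || dropout_rate >= 1)
    stop("dropout_rate must be in [0, 1)")
  structure(list(n_genes = as.integer(n_genes),
                 n_cells = as.integer(n_cells), k = as.integer(k),
                 class_proportions = class_proportions,
                 n_marker_genes = as.integer(n_marker_genes),
                 effect_size = effect_size, base_mean = base_mean,
                 dispersion = dispersion, dropout_rate = dropout_rate,
                 seed = as.integer(seed), mode = mode),
            class = "synthetic_spec")
}

#' Generate a labeled synthetic count matrix
#'
#' Draws raw counts from the generative model described by a
#' [synthetic_spec()]: class `c`'s marker block (genes
#' `(c-1)*m+1 .. c*m`) has mean `base_mean * exp(effect_size)` in cells of
#' class `c` and `base_mean` elsewhere; counts are negative-binomial with
#' the given dispersion (or rounded Gaussian in `"gaussian"` mode) and
#' entries are zeroed independently with probability `dropout_rate`.
#' Fully reproducible from `spec$seed`.
#'
#' @param spec A [synthetic_spec()].
#' @return A [labeled_dataset()] of raw counts with classes
#'   `type1..typek`.
#' @export
simulate_cells <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(spec$seed)
  n <- spec$n_cells; p <- spec$n_genes; k <- spec$k
  counts_per_class <- diff(round(cumsum(c(0, spec$class_proportions)) * n))
  counts_per_class <- as.integer(counts_per_class)
  labels <- rep(seq_len(k), counts_per_class)
  mu <- matrix(spec$base_mean, p, n)
  m <- spec$n_marker_genes
  for (c in seq_len(k)) {
    rows <- ((c - 1L) * m + 1L):(c * m)
    mu[rows, labels == c] <- spec$base_mean * exp(spec$effect_size)
  }
  vals <- if (spec$mode == "nb") {
    matrix(stats::rnbinom(p * n, size = spec$dispersion, mu = as.vector(mu)),
           p, n)
  } else {
    matrix(pmax(0, round(stats::rnorm(p * n, mean = as.vector(mu),
                                      sd = sqrt(as.vector(mu))))), p, n)
  }
  if (spec$dropout_rate > 0)
    vals[stats::runif(p * n) < spec$dropout_rate] <- 0
  em <- expression_matrix(vals,
                          sprintf("G%05d", seq_len(p)),
                          sprintf("cell%06d", seq_len(n)))
  labeled_dataset(em, sprintf("type%d", labels),
                  sprintf("type%d", seq_len(k)))
}

#' Write a labeled dataset to disk in the formats the readers accept
#'
#' @param data A [labeled_dataset()].
#' @param dir Output directory.
#' @param format `"csv"` (dense `matrix.csv`) or `"mtx"`
#'   (`matrix.mtx` + `features.tsv` + `barcodes.tsv`); `labels.csv` is
#'   written either way.
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(data, dir, format = c("csv", "mtx")) {
  format <- match.arg(format)
  stopifnot(inherits(data, "labeled_dataset"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  if (format == "csv") {
    write_expression_csv(data$matrix, file.path(dir, "matrix.csv"))
  } else {
    write_expression_mtx(data$matrix, dir)
  }
  write_cell_labels(data, file.path(dir, "labels.csv"))
  invisible(dir)
}

#' Read a dataset previously written by [write_dataset()]
#'
#' @param dir Directory holding the files.
#' @param format `"csv"` or `"mtx"`; default auto-detects.
#' @param normalized Passed to the matrix reader.
#' @return A [labeled_dataset()].
#' @export
read_dataset <- function(dir, format = NULL, normalized = FALSE) {
  if (is.null(format))
    format <- if (file.exists(file.path(dir, "matrix.mtx"))) "mtx" else "csv"
  em <- if (format == "mtx") {
    read_expression_mtx(file.path(dir, "matrix.mtx"),
                        file.path(dir, "features.tsv"),
                        file.path(dir, "barcodes.tsv"),
                        normalized = normalized)
  } else {
    read_expression_csv(file.path(dir, "matrix.csv"),
                        normalized = normalized)
  }
  attach_labels(em, read_cell_labels(file.path(dir, "labels.csv")))
}
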