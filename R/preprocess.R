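#' Clean gene symbols
#'
#' Removes genes absent from an optional reference symbol set (e.g. current
#' NCBI gene symbols) and drops every copy of a duplicated symbol, since a
#' repeated symbol cannot be attributed to a single gene. Gene order is
#' otherwise preserved.
#'
#' @param matrix An [expression_matrix()].
#' @param reference_symbols Optional character vector of accepted symbols;
#'   when `NULL` only de-duplication is performed.
#' @return The cleaned [expression_matrix()] with unique symbols.
#' @export
clean_gene_symbols <- function(matrix, reference_symbols = NULL) {
  stopifnot(inherits(matrix, "expression_matrix"))
  keep <- rep(TRUE, n_genes(matrix))
  if (!is.null(reference_symbols))
    keep <- keep & matrix$gene_symbols %in% as.character(reference_symbols)
  dup <- matrix$gene_symbols %in%
    matrix$gene_symbols[duplicated(matrix$gene_symbols)]
  keep <- keep & !dup
  if (!any(keep)) stop("gene-symbol cleaning removed every gene")
  em_subset(matrix, genes = which(keep))
}

#' Per-cell global-scaling log-normalisation
#'
#' Each cell's counts are divided by the cell total, multiplied by
#' `scale_factor`, and mapped through `log(1 + x)` (the LogNormalize
#' convention). All-zero cells stay all-zero.
#'
#' @param matrix A raw-count [expression_matrix()].
#' @param scale_factor Positive scale, default `1e4`.
#' @return The normalised [expression_matrix()] with `normalized = TRUE`.
#' @export
log_normalize <- function(matrix, scale_factor = 1e4) {
  stopifnot(inherits(matrix, "expression_matrix"))
  if (matrix$normalized) stop("matrix is already normalized")
  if (!is.numeric(scale_factor) || length(scale_factor) != 1 ||
      scale_factor <= 0)
    stop("scale_factor must be a single positive number")
  v <- matrix$values
  if (any(v < 0)) stop("raw counts must be non-negative")
  s <- colSums(v)
  nz <- s > 0
  v[, nz] <- log1p(sweep(v[, nz, drop = FALSE], 2, s[nz] / scale_factor,
                         "/"))
  expression_matrix(v, matrix$gene_symbols, matrix$cell_ids,
                    normalized = TRUE)
}

#' Remove rare cell types
#'
#' Drops every cell type represented by fewer than `min_fraction` of the
#' total cells (strictly fewer: a type sitting exactly on the threshold is
#' kept), together with its cells. The class vocabulary is re-indexed
#' densely; the relative order of surviving cells is preserved.
#'
#' @param data A [labeled_dataset()].
#' @param min_fraction Fraction of total cells below which a type is
#'   removed; default 0.005 (5 per mille).
#' @return The filtered [labeled_dataset()].
#' @export
filter_rare_cell_types <- function(data, min_fraction = 0.005) {
  stopifnot(inherits(data, "labeled_dataset"))
  if (!is.numeric(min_fraction) || min_fraction < 0 || min_fraction >= 1)
    stop("min_fraction must be in [0, 1)")
  n <- n_cells(data$matrix)
  counts <- tabulate(data$labels, nbins = length(data$class_names))
  keep_class <- counts >= min_fraction * n
  if (sum(keep_class) < 2)
    stop("fewer than 2 cell types survive the rare-type filter")
  keep_cells <- which(keep_class[data$labels])
  new_names <- data$class_names[keep_class]
  labeled_dataset(em_subset(data$matrix, cells = keep_cells),
                  data$class_names[data$labels[keep_cells]], new_names)
}

#' Remove genes with zero total expression
#'
#' With a single matrix, drops genes whose expression is zero across all
#' cells. With a pair, the gene universes are first intersected by symbol
#' and only genes with zero expression in *both* matrices are dropped, so
#' the two returned matrices share an identical gene list.
#'
#' @param a An [expression_matrix()].
#' @param b Optional second [expression_matrix()].
#' @return `a` filtered, or `list(a = , b = )` when `b` is given.
#' @export
remove_zero_genes <- function(a, b = NULL) {
  stopifnot(inherits(a, "expression_matrix"))
  if (is.null(b)) {
    keep <- rowSums(abs(a$values)) > 0
    if (!any(keep)) stop("all genes have zero expression")
    return(em_subset(a, genes = which(keep)))
  }
  stopifnot(inherits(b, "expression_matrix"))
  shared <- intersect(a$gene_symbols, b$gene_symbols)
  if (!length(shared)) stop("gene universes do not intersect")
  a <- em_subset(a, genes = match(shared, a$gene_symbols))
  b <- em_subset(b, genes = match(shared, b$gene_symbols))
  keep <- (rowSums(abs(a$values)) + rowSums(abs(b$values))) > 0
  if (!any(keep)) stop("all shared genes have zero expression")
  list(a = em_subset(a, genes = which(keep)),
       b = em_subset(b, genes = which(keep)))
}

#' Harmonise a cross-dataset train/test pair
#'
#' Prepares two independently collected labeled datasets for train-on-one,
#' predict-on-the-other use: keeps only cell types present in both (one
#' shared vocabulary ordering), removes from the test set any cell whose
#' identifier also appears in the training set, and removes genes with zero
#' expression in both.
#'
#' @param train,test [labeled_dataset()] objects.
#' @return `list(train = , test = )`, harmonised.
#' @export
harmonize_pair <- function(train, test) {
  stopifnot(inherits(train, "labeled_dataset"),
            inherits(test, "labeled_dataset"))
  shared_types <- intersect(train$class_names, test$class_names)
  if (!length(shared_types)) stop("no cell types shared between datasets")
  keep_type <- function(d)
    ld_subset_cells(d, which(d$class_names[d$labels] %in% shared_types))
  tr <- keep_type(train); te <- keep_type(test)
  tr <- labeled_dataset(tr$matrix, tr$class_names[tr$labels], shared_types)
  te <- labeled_dataset(te$matrix, te$class_names[te$labels], shared_types)
  dup <- te$matrix$cell_ids %in% tr$matrix$cell_ids
  if (all(dup)) stop("every test cell also appears in the training set")
  if (any(dup)) te <- ld_subset_cells(te, which(!dup))
  mats <- remove_zero_genes(tr$matrix, te$matrix)
  list(train = labeled_dataset(mats$a, tr$class_names[tr$labels],
                               shared_types),
       test = labeled_dataset(mats$b, te$class_names[te$labels],
                              shared_types))
}

#' Random train/test split
#'
#' Splits a labeled dataset into training and test parts, by default
#' stratified per class so every cell type is represented in both parts at
#' close to the requested fraction. Reproducible for a given seed.
#'
#' @param data A [labeled_dataset()].
#' @param train_fraction Fraction assigned to training, default 0.8.
#' @param seed Integer seed.
#' @param stratified Stratify by cell type (default `TRUE`).
#' @return A list of class `"split_dataset"` with elements `train`, `test`
#'   (both [labeled_dataset()]), `seed` and `train_fraction`.
#' @export
split_train_test <- function(data, train_fraction = 0.8, seed = 1L,
                             stratified = TRUE) {
  stopifnot(inherits(data, "labeled_dataset"))
  if (!is.numeric(train_fraction) || train_fraction <= 0 ||
      train_fraction >= 1)
    stop("train_fraction must be in (0, 1)")
  n <- n_cells(data$matrix)
  k <- length(data$class_names)
  set.seed(as.integer(seed))
  if (stratified) {
    counts <- tabulate(data$labels, nbins = k)
    small <- which(counts < 2L)
    if (length(small))
      stop("cannot stratify: class(es) with fewer than 2 cells: ",
           paste(data$class_names[small], collapse = ", "))
    train_idx <- integer(0)
    for (c in seq_len(k)) {
      cells <- which(data$labels == c)
      n_tr <- max(1L, min(length(cells) - 1L,
                          round(train_fraction * length(cells))))
      train_idx <- c(train_idx, sample(cells, n_tr))
    }
  } else {
    n_tr <- max(1L, min(n - 1L, round(train_fraction * n)))
    train_idx <- sample.int(n, n_tr)
  }
  train_idx <- sort(train_idx)
  test_idx <- setdiff(seq_len(n), train_idx)
  structure(list(train = ld_subset_cells(data, train_idx),
                 test = ld_subset_cells(data, test_idx),
                 seed = as.integer(seed),
                 train_fraction = train_fraction),
            class = "split_dataset")
}

#' @export
print.split_dataset <- function(x, ...) {
  cat(sprintf("split_dataset: %d train / %d test cells (fraction %.2f, seed %d)\n",
              n_cells(x$train$matrix), n_cells(x$test$matrix),
              x$train_fraction, x$seed))
  invisible(x)
}
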