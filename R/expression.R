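#' Construct a genes-by-cells expression matrix
#'
#' The basic data carrier of the package: a dense numeric matrix with genes
#' in rows and cells in columns, together with the gene symbols, the cell
#' identifiers and a flag recording whether the values have already been
#' log-normalised.
#'
#' @param values Numeric matrix, `n_genes x n_cells`. Raw counts must be
#'   non-negative; normalised values may be any finite numbers.
#' @param gene_symbols Character vector of length `nrow(values)`.
#' @param cell_ids Character vector of length `ncol(values)`; must be unique.
#' @param normalized Logical flag; `TRUE` once [log_normalize()] has run.
#' @return An object of class `"expression_matrix"`.
#' @seealso [labeled_dataset()], [read_expression_csv()],
#'   [read_expression_mtx()]
#' @export
expression_matrix <- function(values, gene_symbols, cell_ids,
                              normalized = FALSE) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  gene_symbols <- as.character(gene_symbols)
  cell_ids <- as.character(cell_ids)
  if (nrow(values) != length(gene_symbols))
    stop("nrow(values) [", nrow(values), "] does not match gene_symbols [",
         length(gene_symbols), "]")
  if (ncol(values) != length(cell_ids))
    stop("ncol(values) [", ncol(values), "] does not match cell_ids [",
         length(cell_ids), "]")
  if (anyNA(values) || any(!is.finite(values)))
    stop("expression values must be finite and non-missing")
  if (anyDuplicated(cell_ids))
    stop("cell_ids must be unique")
  dimnames(values) <- list(gene_symbols, cell_ids)
  structure(
    list(values = values, gene_symbols = gene_symbols, cell_ids = cell_ids,
         normalized = isTRUE(normalized)),
    class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("expression_matrix: %d genes x %d cells (%s)\n",
              nrow(x$values), ncol(x$values),
              if (x$normalized) "normalized" else "raw"))
  invisible(x)
}

#' @export
dim.expression_matrix <- function(x) dim(x$values)

n_genes <- function(x) nrow(x$values)
n_cells <- function(x) ncol(x$values)

# subset an expression_matrix, keeping metadata in sync
em_subset <- function(x, genes = NULL, cells = NULL) {
  gi <- if (is.null(genes)) seq_len(n_genes(x)) else genes
  ci <- if (is.null(cells)) seq_len(n_cells(x)) else cells
  expression_matrix(x$values[gi, ci, drop = FALSE],
                    x$gene_symbols[gi], x$cell_ids[ci],
                    normalized = x$normalized)
}

#' Pair an expression matrix with per-cell type labels
#'
#' @param matrix An [expression_matrix()].
#' @param labels Cell-type labels, one per cell: a factor, a character
#'   vector, or integer indices into `class_names`.
#' @param class_names Optional ordered character vector of the `k` distinct
#'   cell-type names. Defaults to the sorted unique labels.
#' @return An object of class `"labeled_dataset"` with integer `labels` in
#'   `1..k` and the ordered `class_names` vocabulary.
#' @export
labeled_dataset <- function(matrix, labels, class_names = NULL) {
  stopifnot(inherits(matrix, "expression_matrix"))
  if (length(labels) != n_cells(matrix))
    stop("labels length [", length(labels),
         "] does not match cell count [", n_cells(matrix), "]")
  if (is.numeric(labels)) {
    if (is.null(class_names))
      stop("class_names is required when labels are numeric indices")
    idx <- as.integer(labels)
  } else {
    labels <- as.character(labels)
    if (is.null(class_names)) class_names <- sort(unique(labels))
    idx <- match(labels, class_names)
    if (anyNA(idx))
      stop("labels contain types absent from class_names: ",
           paste(unique(labels[is.na(idx)]), collapse = ", "))
  }
  class_names <- as.character(class_names)
  if (anyDuplicated(class_names)) stop("class_names must be distinct")
  if (any(idx < 1L | idx > length(class_names)))
    stop("label indices out of range 1..k")
  structure(list(matrix = matrix, labels = idx, class_names = class_names),
            class = "labeled_dataset")
}

#' @export
print.labeled_dataset <- function(x, ...) {
  cat(sprintf("labeled_dataset: %d genes x %d cells, %d cell types\n",
              n_genes(x$matrix), n_cells(x$matrix), length(x$class_names)))
  tab <- table(factor(x$class_names[x$labels], levels = x$class_names))
  print(tab)
  invisible(x)
}

# drop cells by index, keeping labels aligned
ld_subset_cells <- function(data, cells) {
  labeled_dataset(em_subset(data$matrix, cells = cells),
                  data$labels[cells], data$class_names)
}

#' Read a dense expression matrix from CSV/TSV
#'
#' Expects a header row of cell identifiers and a first column of gene
#' symbols, one value per (gene, cell).
#'
#' @param path File path. Tab separation is assumed for `.tsv`/`.tab`
#'   extensions, comma otherwise; override with `sep`.
#' @param sep Field separator; `NULL` picks it from the extension.
#' @param normalized Logical; set `TRUE` if the file already holds
#'   log-normalised values.
#' @return An [expression_matrix()].
#' @export
read_expression_csv <- function(path, sep = NULL, normalized = FALSE) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (is.null(sep))
    sep <- if (grepl("\\.(tsv|tab)$", path, ignore.case = TRUE)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          check.names = FALSE, stringsAsFactors = FALSE,
                          quote = "\"", comment.char = "")
  if (ncol(df) < 2) stop("expression table needs a gene column plus cells: ",
                         path)
  genes <- as.character(df[[1]])
  vals <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(vals)) stop("non-numeric expression values in ", path)
  expression_matrix(vals, genes, colnames(df)[-1], normalized = normalized)
}

#' Read a sparse expression matrix in MatrixMarket form
#'
#' Reads a genes-by-cells MTX file (1-based indices per the MatrixMarket
#' standard) with `features.tsv`/`barcodes.tsv` sidecars holding the gene
#' symbols and the cell identifiers, one per line.
#'
#' @param mtx_path Path to the `.mtx` file.
#' @param features_path Path to the gene-symbol sidecar (first column used).
#' @param barcodes_path Path to the cell-identifier sidecar.
#' @param normalized Logical; see [read_expression_csv()].
#' @return An [expression_matrix()] (densified).
#' @export
read_expression_mtx <- function(mtx_path, features_path, barcodes_path,
                                normalized = FALSE) {
  for (p in c(mtx_path, features_path, barcodes_path))
    if (!file.exists(p)) stop("no such file: ", p)
  m <- as.matrix(Matrix::readMM(mtx_path))
  feats <- utils::read.table(features_path, header = FALSE, sep = "\t",
                             stringsAsFactors = FALSE)[[1]]
  bars <- utils::read.table(barcodes_path, header = FALSE, sep = "\t",
                            stringsAsFactors = FALSE)[[1]]
  if (nrow(m) != length(feats))
    stop("MTX has ", nrow(m), " rows but features file lists ",
         length(feats), " genes")
  if (ncol(m) != length(bars))
    stop("MTX has ", ncol(m), " columns but barcodes file lists ",
         length(bars), " cells")
  expression_matrix(m, feats, bars, normalized = normalized)
}

#' Read per-cell labels from a two-column CSV
#'
#' @param path CSV with header and columns `cell_id,cell_type`.
#' @return Named character vector of cell types, names are cell ids.
#' @export
read_cell_labels <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (ncol(df) < 2) stop("label file needs cell_id,cell_type columns: ", path)
  stats::setNames(as.character(df[[2]]), as.character(df[[1]]))
}

#' Assemble a labeled dataset from a matrix and a label table
#'
#' Matches labels to cells by identifier and errors on any mismatch, so a
#' shuffled or truncated label file cannot silently misalign.
#'
#' @param matrix An [expression_matrix()].
#' @param labels Named character vector as returned by [read_cell_labels()].
#' @return A [labeled_dataset()].
#' @export
attach_labels <- function(matrix, labels) {
  stopifnot(inherits(matrix, "expression_matrix"))
  miss <- setdiff(matrix$cell_ids, names(labels))
  if (length(miss))
    stop("no label for ", length(miss), " cell(s), e.g. ",
         paste(utils::head(miss, 3), collapse = ", "))
  labeled_dataset(matrix, unname(labels[matrix$cell_ids]))
}

#' Write an expression matrix as dense CSV
#'
#' Inverse of [read_expression_csv()]; first column `gene`, then one column
#' per cell.
#'
#' @param x An [expression_matrix()].
#' @param path Output path.
#' @export
write_expression_csv <- function(x, path) {
  stopifnot(inherits(x, "expression_matrix"))
  df <- data.frame(gene = x$gene_symbols, x$values, check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df) <- c("gene", x$cell_ids)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write an expression matrix as MTX plus sidecars
#'
#' @param x An [expression_matrix()].
#' @param dir Output directory; creates `matrix.mtx`, `features.tsv`,
#'   `barcodes.tsv`.
#' @return The directory, invisibly.
#' @export
write_expression_mtx <- function(x, dir) {
  stopifnot(inherits(x, "expression_matrix"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  Matrix::writeMM(Matrix::Matrix(x$values, sparse = TRUE),
                  file.path(dir, "matrix.mtx"))
  writeLines(x$gene_symbols, file.path(dir, "features.tsv"))
  writeLines(x$cell_ids, file.path(dir, "barcodes.tsv"))
  invisible(dir)
}

#' Write per-cell labels as a two-column CSV
#'
#' @param data A [labeled_dataset()].
#' @param path Output path.
#' @export
write_cell_labels <- function(data, path) {
  stopifnot(inherits(data, "labeled_dataset"))
  utils::write.csv(
    data.frame(cell_id = data$matrix$cell_ids,
               cell_type = data$class_names[data$labels]),
    path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
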