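#' Construct a single-cell UMI count dataset
#'
#' The universal carrier for single-cell data in this package: a sparse
#' cells x genes UMI count matrix with per-cell metadata and (optionally) a
#' log-normalized matrix of the same shape.
#'
#' @param counts Non-negative integer matrix, cells in rows, genes in columns.
#'   Coerced to a sparse \code{dgCMatrix}.
#' @param gene_names Character vector of unique gene names (columns). Taken
#'   from \code{colnames(counts)} if missing.
#' @param cell_ids Character vector of unique cell barcodes (rows). Taken
#'   from \code{rownames(counts)} if missing.
#' @param cell_meta Optional data.frame of per-cell metadata (e.g. sample and
#'   treatment-stage labels), one row per cell, aligned to \code{cell_ids}.
#' @param normalized Optional real matrix aligned to \code{counts}; usually
#'   produced by \code{\link{normalize_log}}.
#'
#' @return An object of class \code{cell_dataset}: a list with elements
#'   \code{counts}, \code{gene_names}, \code{cell_ids}, \code{cell_meta},
#'   \code{normalized}.
#' @export
cell_dataset <- function(counts, gene_names = NULL, cell_ids = NULL,
                         cell_meta = NULL, normalized = NULL) {
  if (!inherits(counts, "Matrix"))
    counts <- Matrix::Matrix(counts, sparse = TRUE)
  counts <- methods::as(methods::as(methods::as(counts, "dMatrix"),
                                    "generalMatrix"), "CsparseMatrix")
  if (is.null(gene_names)) gene_names <- colnames(counts)
  if (is.null(cell_ids)) cell_ids <- rownames(counts)
  if (is.null(gene_names) || is.null(cell_ids))
    stop("gene_names and cell_ids must be supplied or present as dimnames")
  gene_names <- as.character(gene_names)
  cell_ids <- as.character(cell_ids)
  if (length(gene_names) != ncol(counts))
    stop("gene_names length does not match the number of genes")
  if (length(cell_ids) != nrow(counts))
    stop("cell_ids length does not match the number of cells")
  if (anyDuplicated(gene_names)) stop("gene names must be unique")
  if (anyDuplicated(cell_ids)) stop("cell barcodes must be unique")
  x <- counts@x
  if (length(x) && (any(x < 0) || any(x != round(x))))
    stop("counts must be non-negative integers")
  dimnames(counts) <- list(cell_ids, gene_names)
  if (is.null(cell_meta)) {
    cell_meta <- data.frame(row.names = cell_ids)
  } else {
    cell_meta <- as.data.frame(cell_meta)
    if (nrow(cell_meta) != length(cell_ids))
      stop("cell_meta must have one row per cell")
    rownames(cell_meta) <- cell_ids
  }
  if (!is.null(normalized)) {
    if (!all(dim(normalized) == dim(counts)))
      stop("normalized matrix must match counts dimensions")
    dimnames(normalized) <- dimnames(counts)
  }
  structure(
    list(counts = counts, gene_names = gene_names, cell_ids = cell_ids,
         cell_meta = cell_meta, normalized = normalized),
    class = "cell_dataset"
  )
}

#' @method print cell_dataset
#' @export
print.cell_dataset <- function(x, ...) {
  cat(sprintf("cell_dataset: %d cells x %d genes (%s)\n",
              n_cells(x), n_genes(x),
              if (is.null(x$normalized)) "raw counts" else
                "counts + normalized"))
  if (ncol(x$cell_meta))
    cat("  cell_meta:", paste(colnames(x$cell_meta), collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.cell_dataset <- function(x) dim(x$counts)

#' Number of cells / genes in a dataset
#' @param x A \code{cell_dataset}.
#' @return Integer count.
#' @export
n_cells <- function(x) nrow(x$counts)

#' @rdname n_cells
#' @export
n_genes <- function(x) ncol(x$counts)

#' Subset a dataset by cells and/or genes
#'
#' Keeps counts, normalized data and metadata aligned. Order of the supplied
#' indices is preserved.
#'
#' @param x A \code{cell_dataset}.
#' @param cells,genes Logical, integer or character indices; \code{NULL}
#'   keeps everything.
#' @return A \code{cell_dataset}.
#' @export
subset_cells <- function(x, cells = NULL, genes = NULL) {
  if (is.null(cells)) cells <- seq_len(n_cells(x))
  if (is.null(genes)) genes <- seq_len(n_genes(x))
  cell_dataset(
    counts = x$counts[cells, genes, drop = FALSE],
    cell_meta = x$cell_meta[cells, , drop = FALSE],
    normalized = if (!is.null(x$normalized))
      x$normalized[cells, genes, drop = FALSE]
  )
}

# Genes treated as mitochondrial by the 10x naming convention.
mito_genes <- function(x, prefix = "MT-") {
  startsWith(x$gene_names, prefix)
}

#' Per-cell mitochondrial UMI fraction
#'
#' Mitochondrial genes are recognized by name prefix (default \code{"MT-"},
#' the 10x convention). Cells with zero total counts get fraction 0.
#'
#' @param x A \code{cell_dataset}.
#' @param prefix Gene-name prefix identifying mitochondrial genes.
#' @return Numeric vector, one fraction in [0, 1] per cell.
#' @export
mito_fraction <- function(x, prefix = "MT-") {
  mt <- mito_genes(x, prefix)
  tot <- Matrix::rowSums(x$counts)
  mito <- if (any(mt)) Matrix::rowSums(x$counts[, mt, drop = FALSE]) else
    numeric(n_cells(x))
  ifelse(tot > 0, mito / tot, 0)
}
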