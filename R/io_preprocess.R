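#' QC thresholds for cell and gene filtering
#'
#' Defaults follow common 10x practice for peripheral-blood data: keep cells
#' with at least 200 detected genes and at most 5\% mitochondrial UMIs, and
#' genes detected in at least 3 cells. All boundaries are inclusive for
#' retention.
#'
#' @param min_genes_per_cell Minimum detected genes per retained cell.
#' @param min_cells_per_gene Minimum cells in which a retained gene is
#'   detected (count > 0).
#' @param max_mito_fraction Maximum mitochondrial UMI fraction per retained
#'   cell, in [0, 1].
#' @return A \code{qc_thresholds} list.
#' @export
qc_thresholds <- function(min_genes_per_cell = 200, min_cells_per_gene = 3,
                          max_mito_fraction = 0.05) {
  stopifnot(min_genes_per_cell >= 0, min_cells_per_gene >= 0,
            max_mito_fraction >= 0, max_mito_fraction <= 1)
  structure(list(min_genes_per_cell = min_genes_per_cell,
                 min_cells_per_gene = min_cells_per_gene,
                 max_mito_fraction = max_mito_fraction),
            class = "qc_thresholds")
}

#' Write a dataset in 10x convention (MTX + genes.tsv + barcodes.tsv)
#'
#' The Matrix Market file stores genes as rows and cells as columns, as
#' CellRanger does; the in-memory orientation (cells x genes) is transposed
#' on the way out and back. Per-cell metadata, if present, is written as
#' \code{cell_meta.tsv} keyed by barcode.
#'
#' @param dataset A \code{\link{cell_dataset}}.
#' @param path Directory to write into (created if absent).
#' @return \code{path}, invisibly.
#' @export
write_10x <- function(dataset, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  Matrix::writeMM(Matrix::t(dataset$counts), file.path(path, "matrix.mtx"))
  utils::write.table(
    data.frame(gene_id = dataset$gene_names, gene_name = dataset$gene_names),
    file.path(path, "genes.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  writeLines(dataset$cell_ids, file.path(path, "barcodes.tsv"))
  if (ncol(dataset$cell_meta) > 0) {
    meta <- cbind(barcode = dataset$cell_ids, dataset$cell_meta)
    utils::write.table(meta, file.path(path, "cell_meta.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Read a dataset written in 10x convention
#'
#' @param path Directory containing \code{matrix.mtx}, \code{genes.tsv} and
#'   \code{barcodes.tsv} (and optionally \code{cell_meta.tsv}).
#' @return A \code{\link{cell_dataset}}.
#' @export
read_10x <- function(path) {
  mtx_file <- file.path(path, "matrix.mtx")
  if (!file.exists(mtx_file)) stop("no matrix.mtx under ", path)
  m <- Matrix::t(Matrix::readMM(mtx_file))
  genes <- utils::read.table(file.path(path, "genes.tsv"), sep = "\t",
                             stringsAsFactors = FALSE)
  barcodes <- readLines(file.path(path, "barcodes.tsv"))
  if (nrow(genes) != ncol(m))
    stop("genes.tsv has ", nrow(genes), " entries but matrix has ",
         ncol(m), " genes")
  if (length(barcodes) != nrow(m))
    stop("barcodes.tsv has ", length(barcodes), " entries but matrix has ",
         nrow(m), " cells")
  if (anyDuplicated(barcodes)) stop("duplicate barcodes in barcodes.tsv")
  gene_names <- genes[[min(2, ncol(genes))]]
  meta_file <- file.path(path, "cell_meta.tsv")
  meta <- NULL
  if (file.exists(meta_file)) {
    meta <- utils::read.table(meta_file, sep = "\t", header = TRUE,
                              stringsAsFactors = FALSE)
    if (!identical(as.character(meta$barcode), barcodes))
      stop("cell_meta.tsv barcodes do not match barcodes.tsv")
    meta <- meta[, setdiff(colnames(meta), "barcode"), drop = FALSE]
  }
  cell_dataset(m, gene_names = gene_names, cell_ids = barcodes,
               cell_meta = meta)
}

#' Filter cells on detected genes and mitochondrial fraction
#'
#' Retains cells with at least \code{min_genes_per_cell} detected genes
#' (count > 0) and mitochondrial UMI fraction at most
#' \code{max_mito_fraction}. Mitochondrial genes are identified by the
#' \code{"MT-"} name prefix; if none are present the mito filter removes
#' nothing. Cell order is preserved.
#'
#' @param dataset A \code{\link{cell_dataset}}.
#' @param thresholds A \code{\link{qc_thresholds}}.
#' @return The filtered \code{cell_dataset} (possibly empty).
#' @export
filter_cells <- function(dataset, thresholds = qc_thresholds()) {
  detected <- Matrix::rowSums(dataset$counts > 0)
  keep <- detected >= thresholds$min_genes_per_cell &
    mito_fraction(dataset) <= thresholds$max_mito_fraction
  subset_cells(dataset, cells = which(keep))
}

#' Filter genes on the number of cells in which they are detected
#'
#' Retains genes detected (count > 0) in at least
#' \code{min_cells_per_gene} cells. Idempotent; gene order preserved.
#'
#' @inheritParams filter_cells
#' @return The filtered \code{cell_dataset}.
#' @export
filter_genes <- function(dataset, thresholds = qc_thresholds()) {
  n_detected <- Matrix::colSums(dataset$counts > 0)
  subset_cells(dataset, genes = which(n_detected >= thresholds$min_cells_per_gene))
}

#' Log-normalize UMI counts
#'
#' Per cell: \code{log(1 + count / total * scale_factor)} (natural log),
#' the standard depth normalization for UMI data. Cells with zero total
#' counts yield all-zero rows.
#'
#' @param dataset A \code{\link{cell_dataset}}.
#' @param scale_factor Library-size target, default 10,000.
#' @return The dataset with its \code{normalized} slot filled.
#' @export
normalize_log <- function(dataset, scale_factor = 1e4) {
  stopifnot(scale_factor > 0)
  tot <- Matrix::rowSums(dataset$counts)
  scl <- ifelse(tot > 0, scale_factor / tot, 0)
  # dgCMatrix stores entries by column; @i holds each entry's 0-based row
  # (cell) index, which picks that cell's depth scale.
  norm <- dataset$counts
  norm@x <- log1p(norm@x * scl[norm@i + 1L])
  dataset$normalized <- norm
  dataset
}

# Dense normalized matrix (cells x genes); errors if normalization missing.
norm_matrix <- function(dataset) {
  if (is.null(dataset$normalized))
    stop("dataset has no normalized data; run normalize_log() first")
  dataset$normalized
}
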