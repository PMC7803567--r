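#' Marker / differential-expression detection by Wilcoxon rank-sum test
#'
#' For each gene expressed in at least \code{min_pct} of either group, tests
#' in-group vs out-group normalized expression with a two-sided Wilcoxon
#' rank-sum test and corrects across tested genes by Benjamini-Hochberg.
#' The log2 fold change is computed on depth-normalized (expm1-transformed)
#' means with pseudocount 1, the usual single-cell convention.
#'
#' @param dataset A normalized \code{\link{cell_dataset}}.
#' @param clusters Factor of cluster labels named by cell id (or a
#'   \code{cluster_assignment}).
#' @param target Either a single cluster label (that cluster vs all other
#'   cells) or a list of two character vectors of cell ids
#'   (\code{list(group1, group2)}).
#' @param min_pct Minimum expression fraction in either group for a gene to
#'   be tested.
#' @return A \code{data.frame} (MarkerTable) with columns \code{gene},
#'   \code{cluster}, \code{log2_fold_change}, \code{p_value}, \code{fdr},
#'   \code{pct_in}, \code{pct_out}, ordered by p-value.
#' @export
find_markers <- function(dataset, clusters, target, min_pct = 0.10) {
  X <- norm_matrix(dataset)
  clusters <- as_cluster_factor(clusters, dataset$cell_ids)
  if (is.list(target)) {
    stopifnot(length(target) == 2)
    in_ids <- match(target[[1]], dataset$cell_ids)
    out_ids <- match(target[[2]], dataset$cell_ids)
    if (anyNA(in_ids) || anyNA(out_ids))
      stop("target cell ids absent from the dataset")
    label <- "group1"
  } else {
    if (!target %in% levels(clusters))
      stop("unknown cluster label: ", target)
    in_ids <- which(clusters == target)
    out_ids <- which(clusters != target)
    label <- as.character(target)
  }
  if (length(in_ids) < 3 || length(out_ids) < 3)
    stop("each group must contain at least 3 cells")
  Xi <- X[in_ids, , drop = FALSE]
  Xo <- X[out_ids, , drop = FALSE]
  pct_in <- Matrix::colMeans(Xi > 0)
  pct_out <- Matrix::colMeans(Xo > 0)
  tested <- which(pct_in >= min_pct | pct_out >= min_pct)
  mean_in <- Matrix::colMeans(expm1(Xi))
  mean_out <- Matrix::colMeans(expm1(Xo))
  l2fc <- log2((mean_in + 1) / (mean_out + 1))
  p <- vapply(tested, function(g)
    stats::wilcox.test(as.numeric(Xi[, g]), as.numeric(Xo[, g]))$p.value,
    numeric(1))
  res <- data.frame(
    gene = dataset$gene_names[tested],
    cluster = label,
    log2_fold_change = l2fc[tested],
    p_value = p,
    fdr = stats::p.adjust(p, method = "BH"),
    pct_in = pct_in[tested],
    pct_out = pct_out[tested],
    row.names = NULL, stringsAsFactors = FALSE)
  res[order(res$p_value, -abs(res$log2_fold_change)), , drop = FALSE]
}

#' Markers of every cluster against the rest
#'
#' @inheritParams find_markers
#' @return Row-bound MarkerTable over all cluster levels.
#' @export
find_all_markers <- function(dataset, clusters, min_pct = 0.10) {
  clusters <- as_cluster_factor(clusters, dataset$cell_ids)
  do.call(rbind, lapply(levels(clusters), function(lv)
    find_markers(dataset, clusters, target = lv, min_pct = min_pct)))
}

as_cluster_factor <- function(clusters, cell_ids) {
  if (inherits(clusters, "cluster_assignment")) clusters <- clusters$cluster
  clusters <- as.factor(clusters)
  if (!is.null(names(clusters))) {
    if (!all(cell_ids %in% names(clusters)))
      stop("cluster labels missing for some cells")
    clusters <- clusters[cell_ids]
  } else if (length(clusters) != length(cell_ids)) {
    stop("cluster vector length does not match the number of cells")
  }
  clusters
}

#' Module score: gene-set expression above expression-matched controls
#'
#' Genes are binned by average normalized expression across all cells; for
#' every gene in the set, control genes are drawn from the same bin. The
#' score is the mean expression of the set minus the mean expression of the
#' pooled control genes, per cell, so a constant matrix scores 0 everywhere.
#'
#' @param dataset A normalized \code{\link{cell_dataset}}.
#' @param gene_set Character vector of gene names (intersected with the
#'   dataset; empty intersection is an error).
#' @param n_bins Expression bins for control matching.
#' @param n_control_per_gene Control genes sampled per set gene (clamped to
#'   bin size; sampling without replacement).
#' @param seed Integer seed for control sampling.
#' @return Numeric score per cell, named by cell id.
#' @export
module_score <- function(dataset, gene_set, n_bins = 24,
                         n_control_per_gene = 100, seed = 0L) {
  X <- norm_matrix(dataset)
  set <- intersect(gene_set, dataset$gene_names)
  if (!length(set))
    stop("gene_set does not intersect the dataset's genes")
  avg <- Matrix::colMeans(X)
  n_bins <- min(n_bins, length(avg))
  # equal-occupancy bins on the rank of average expression
  bin <- ceiling(rank(avg, ties.method = "first") * n_bins / length(avg))
  names(bin) <- dataset$gene_names
  controls <- with_seed(seed, {
    unique(unlist(lapply(set, function(g) {
      pool <- dataset$gene_names[bin == bin[[g]]]
      sample(pool, min(n_control_per_gene, length(pool)))
    })))
  })
  score <- Matrix::rowMeans(X[, set, drop = FALSE]) -
    Matrix::rowMeans(X[, controls, drop = FALSE])
  stats::setNames(as.numeric(score), dataset$cell_ids)
}

#' Cell-cycle phase scores and assignment
#'
#' Scores each cell for the S-phase and G2/M expression programs with
#' \code{\link{module_score}} and assigns a phase: the higher-scoring
#' program if either score is positive, otherwise G1.
#'
#' @param dataset A normalized \code{\link{cell_dataset}}.
#' @param s_genes,g2m_genes Phase gene lists; default to the bundled lists
#'   (see \code{\link{cc_genes}}).
#' @param seed Seed passed to \code{\link{module_score}}.
#' @return \code{data.frame} with \code{s_score}, \code{g2m_score},
#'   \code{phase} (factor G1/S/G2M), rownames are cell ids.
#' @export
cell_cycle_score <- function(dataset, s_genes = NULL, g2m_genes = NULL,
                             seed = 0L) {
  cc <- cc_genes()
  if (is.null(s_genes)) s_genes <- cc$s
  if (is.null(g2m_genes)) g2m_genes <- cc$g2m
  s <- module_score(dataset, s_genes, seed = seed)
  g2m <- module_score(dataset, g2m_genes, seed = seed + 1L)
  phase <- ifelse(pmax(s, g2m) <= 0, "G1", ifelse(s > g2m, "S", "G2M"))
  data.frame(s_score = s, g2m_score = g2m,
             phase = factor(phase, levels = c("G1", "S", "G2M")),
             row.names = dataset$cell_ids)
}

#' Bundled cell-cycle phase gene lists
#'
#' The widely used S-phase (43 genes) and G2/M (54 genes) human gene lists
#' shipped with the package as plain text.
#'
#' @return List with character vectors \code{s} and \code{g2m}.
#' @export
cc_genes <- function() {
  path <- system.file("extdata", "cell_cycle_genes.tsv", package = "cmlsig",
                      mustWork = TRUE)
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  list(s = tab$gene[tab$phase == "S"], g2m = tab$gene[tab$phase == "G2M"])
}
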