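#' Bundled curated ligand-receptor pairs
#'
#' A small curated table of well-established human ligand-receptor pairs
#' relevant to blood/immune cross-talk (including CD99-PILRA and
#' CD52-SIGLEC10), shipped as plain text. It stands in for large external
#' interaction databases, which are out of scope.
#'
#' @return \code{data.frame} with columns \code{pair_id}, \code{ligand},
#'   \code{receptor}.
#' @export
lr_pairs <- function() {
  path <- system.file("extdata", "lr_pairs.tsv", package = "cmlsig",
                      mustWork = TRUE)
  utils::read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
}

#' Fraction of cells in a cluster expressing a gene
#'
#' Expression means count > 0. Used as the gate for the interaction test:
#' a pair is tested only if ligand and receptor are each expressed in
#' strictly more than 30\% of cells of their respective clusters.
#'
#' @param dataset A \code{\link{cell_dataset}}.
#' @param clusters Cluster labels (factor named by cell id, or a
#'   \code{cluster_assignment}).
#' @param gene Gene name.
#' @param cluster_label Cluster of interest.
#' @return Fraction in [0, 1].
#' @export
expressed_fraction <- function(dataset, clusters, gene, cluster_label) {
  clusters <- as_cluster_factor(clusters, dataset$cell_ids)
  if (!gene %in% dataset$gene_names) stop("unknown gene: ", gene)
  cells <- which(clusters == cluster_label)
  if (!length(cells)) stop("unknown or empty cluster: ", cluster_label)
  mean(dataset$counts[cells, gene] > 0)
}

#' Permutation test for a ligand-receptor interaction between two clusters
#'
#' The observed interaction score is the mean of (mean ligand expression in
#' cluster A, mean receptor expression in cluster B), computed on normalized
#' data. The null distribution is built by globally shuffling all cells'
#' cluster labels \code{n_perm} times and recomputing the score; the
#' empirical p is the fraction of permuted scores >= the observed one, with
#' floor 1/n_perm. Pairs failing the 30\% expression gate in either cluster
#' are returned untested (p = NA).
#'
#' @param dataset A normalized \code{\link{cell_dataset}}.
#' @param clusters Cluster labels.
#' @param ligand,receptor Gene names of the pair.
#' @param cluster_a Cluster evaluated for the ligand.
#' @param cluster_b Cluster evaluated for the receptor.
#' @param n_perm Number of label permutations (default 1000).
#' @param seed Integer seed; identical seed gives identical p.
#' @param min_frac Expression-fraction gate (strict; default 0.30).
#' @return List (InteractionResult) with \code{ligand}, \code{receptor},
#'   \code{cluster_a}, \code{cluster_b}, \code{score}, \code{p_value},
#'   \code{tested}, \code{frac_ligand_a}, \code{frac_receptor_b}.
#' @export
lr_permutation_test <- function(dataset, clusters, ligand, receptor,
                                cluster_a, cluster_b, n_perm = 1000,
                                seed = 0L, min_frac = 0.30) {
  clusters <- as_cluster_factor(clusters, dataset$cell_ids)
  X <- norm_matrix(dataset)
  in_a <- clusters == cluster_a
  in_b <- clusters == cluster_b
  if (!any(in_a)) stop("cluster has 0 cells: ", cluster_a)
  if (!any(in_b)) stop("cluster has 0 cells: ", cluster_b)
  fa <- expressed_fraction(dataset, clusters, ligand, cluster_a)
  fb <- expressed_fraction(dataset, clusters, receptor, cluster_b)
  res <- list(ligand = ligand, receptor = receptor,
              cluster_a = as.character(cluster_a),
              cluster_b = as.character(cluster_b),
              score = NA_real_, p_value = NA_real_, tested = FALSE,
              frac_ligand_a = fa, frac_receptor_b = fb)
  if (fa <= min_frac || fb <= min_frac) return(res)
  xl <- as.numeric(X[, ligand])
  xr <- as.numeric(X[, receptor])
  na <- sum(in_a); nb <- sum(in_b); n <- length(xl)
  obs <- (mean(xl[in_a]) + mean(xr[in_b])) / 2
  perm <- with_seed(seed, {
    vapply(seq_len(n_perm), function(i) {
      lab <- sample.int(n)
      ia <- lab[seq_len(na)]
      ib <- lab[na + seq_len(nb)]
      (mean(xl[ia]) + mean(xr[ib])) / 2
    }, numeric(1))
  })
  res$score <- obs
  res$p_value <- max(mean(perm >= obs), 1 / n_perm)
  res$tested <- TRUE
  res
}

#' Test all bundled (or supplied) ligand-receptor pairs between two clusters
#'
#' @inheritParams lr_permutation_test
#' @param pairs \code{data.frame} with \code{ligand}/\code{receptor} columns
#'   (default: bundled \code{\link{lr_pairs}}); pairs whose genes are absent
#'   from the dataset are skipped.
#' @return \code{data.frame} with one row per pair: score, empirical p,
#'   tested flag and expression fractions.
#' @export
lr_test_all <- function(dataset, clusters, cluster_a, cluster_b,
                        pairs = lr_pairs(), n_perm = 1000, seed = 0L,
                        min_frac = 0.30) {
  pairs <- pairs[pairs$ligand %in% dataset$gene_names &
                   pairs$receptor %in% dataset$gene_names, , drop = FALSE]
  rows <- lapply(seq_len(nrow(pairs)), function(i)
    lr_permutation_test(dataset, clusters, pairs$ligand[i],
                        pairs$receptor[i], cluster_a, cluster_b,
                        n_perm = n_perm, seed = seed + i, min_frac = min_frac))
  do.call(rbind, lapply(rows, as.data.frame))
}
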