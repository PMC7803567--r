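#' Principal component analysis of normalized expression
#'
#' Genes are centered and (by default) scaled to unit variance, with scaled
#' values clipped at \code{clip} to prevent outlier domination, then
#' decomposed by SVD. The returned model carries everything needed to place
#' new cells in the same PC space (\code{\link{project_query}} relies on
#' this): the gene subset, per-gene center/scale, and loadings.
#'
#' @param dataset A normalized \code{\link{cell_dataset}}.
#' @param n_components Number of components (<= min(cells, genes)).
#' @param gene_subset Optional character vector of genes to use (e.g. highly
#'   variable genes); default all genes.
#' @param scale. Scale genes to unit variance (zero-variance genes get
#'   scale 1).
#' @param clip Clip scaled values at +/- this bound.
#' @return A \code{pca_model}: list with \code{gene_subset}, \code{center},
#'   \code{scale}, \code{loadings} (genes x components, orthonormal columns),
#'   \code{sdev} (component standard deviations, non-increasing),
#'   \code{scores} (cells x components), \code{scaled}, \code{clip}.
#' @export
fit_pca <- function(dataset, n_components = 30, gene_subset = NULL,
                    scale. = TRUE, clip = 10) {
  X <- norm_matrix(dataset)
  if (!is.null(gene_subset)) {
    missing <- setdiff(gene_subset, dataset$gene_names)
    if (length(missing))
      stop("gene_subset contains genes absent from the dataset")
    X <- X[, gene_subset, drop = FALSE]
  }
  X <- as.matrix(X)
  if (n_components > min(dim(X)))
    stop("n_components exceeds min(cells, genes)")
  ctr <- colMeans(X)
  scl <- if (scale.) {
    s <- apply(X, 2, stats::sd)
    ifelse(s > 0, s, 1)
  } else rep(1, ncol(X))
  Xs <- scale(X, center = ctr, scale = scl)
  Xs[Xs > clip] <- clip
  Xs[Xs < -clip] <- -clip
  sv <- svd(Xs, nu = 0, nv = n_components)
  loadings <- sv$v
  dimnames(loadings) <- list(colnames(X), paste0("PC", seq_len(n_components)))
  scores <- Xs %*% loadings
  rownames(scores) <- dataset$cell_ids
  structure(list(gene_subset = colnames(X), center = ctr, scale = scl,
                 loadings = loadings,
                 sdev = sv$d[seq_len(n_components)] / sqrt(max(1, nrow(X) - 1)),
                 scores = scores, scaled = scale., clip = clip),
            class = "pca_model")
}

# Place new cells into an existing PC space using the model's (reference)
# centering and scaling -- never the query's own statistics.
pca_transform <- function(model, dataset) {
  X <- as.matrix(norm_matrix(dataset)[, model$gene_subset, drop = FALSE])
  Xs <- scale(X, center = model$center, scale = model$scale)
  Xs[Xs > model$clip] <- model$clip
  Xs[Xs < -model$clip] <- -model$clip
  Xs %*% model$loadings
}

# Exact k-nearest-neighbor search: for each row of query, the k nearest rows
# of ref under Euclidean distance, ties broken by reference index (stable).
knn_search <- function(ref, query, k) {
  if (k > nrow(ref)) stop("k exceeds the number of reference points")
  d2 <- outer(rowSums(query^2), rowSums(ref^2), "+") -
    2 * tcrossprod(query, ref)
  d2[d2 < 0] <- 0
  dimnames(d2) <- NULL
  idx <- t(apply(d2, 1, function(row)
    order(row, seq_along(row))[seq_len(k)]))
  if (k == 1) idx <- matrix(idx, ncol = 1)
  dist <- sqrt(t(vapply(seq_len(nrow(query)),
                        function(i) d2[i, idx[i, ]], numeric(k))))
  if (k == 1) dist <- matrix(dist, ncol = 1)
  list(index = idx, dist = dist)
}

#' Graph-based unsupervised clustering of cells in PC space
#'
#' Builds an exact k-nearest-neighbor graph (Euclidean distance in PC space)
#' and partitions it with Louvain modularity optimization at the given
#' resolution. Deterministic for a fixed seed.
#'
#' @param scores Cells x components score matrix (from
#'   \code{\link{fit_pca}}), rownames are cell ids.
#' @param resolution Modularity resolution; larger values give more clusters.
#' @param k_neighbors Neighbors per cell for the graph.
#' @param seed Integer seed for the community search.
#' @return A \code{cluster_assignment}: list with \code{cluster} (factor
#'   named by cell id) and \code{embedding} (cells x 2, the first two score
#'   columns, for visualization).
#' @export
cluster_cells <- function(scores, resolution = 1, k_neighbors = 20,
                          seed = 0L) {
  scores <- as.matrix(scores)
  n <- nrow(scores)
  if (n < k_neighbors + 1)
    stop("need at least k_neighbors + 1 cells")
  nn <- knn_search(scores, scores, k_neighbors + 1L)
  # drop self-matches (a cell is its own nearest neighbor)
  edges <- cbind(rep(seq_len(n), each = k_neighbors + 1L),
                 as.vector(t(nn$index)))
  edges <- edges[edges[, 1] != edges[, 2], , drop = FALSE]
  g <- igraph::simplify(igraph::graph_from_edgelist(edges, directed = FALSE))
  comm <- with_seed(seed,
                    igraph::cluster_louvain(g, resolution = resolution))
  labels <- factor(paste0("C", igraph::membership(comm)))
  names(labels) <- rownames(scores)
  structure(list(cluster = labels,
                 embedding = scores[, seq_len(min(2, ncol(scores))),
                                    drop = FALSE]),
            class = "cluster_assignment")
}
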