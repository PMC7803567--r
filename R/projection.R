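#' Fit a reference map for projecting query cells
#'
#' Selects highly variable genes (HVGs) among the genes shared between
#' reference and query -- by variance of log-normalized expression in the
#' reference -- and fits a PCA on the reference restricted to those genes.
#' The returned map carries the reference scores, embedding and (optional)
#' cluster labels; query cells are later placed in this space using the
#' reference's centering and scaling, never their own.
#'
#' @param reference A normalized \code{\link{cell_dataset}}.
#' @param query_genes Character vector of the query dataset's gene names.
#' @param n_hvg Number of highly variable genes (clamped to the size of the
#'   gene intersection).
#' @param n_pcs Number of principal components (default 30).
#' @param embedding Optional cells x 2 reference embedding (e.g. UMAP/t-SNE
#'   coordinates); defaults to the first two PCs.
#' @param ref_clusters Optional cluster labels for the reference cells.
#' @param scale. Scale genes before PCA (default TRUE).
#' @return A \code{reference_map}: list with \code{pca} (the fitted
#'   \code{pca_model}), \code{ref_scores}, \code{embedding},
#'   \code{ref_clusters}, \code{ref_ids}, \code{hvg}.
#' @export
fit_reference <- function(reference, query_genes, n_hvg = 2000, n_pcs = 30,
                          embedding = NULL, ref_clusters = NULL,
                          scale. = TRUE) {
  shared <- intersect(reference$gene_names, query_genes)
  if (!length(shared))
    stop("reference and query share no genes")
  X <- norm_matrix(reference)[, shared, drop = FALSE]
  v <- apply(as.matrix(X), 2, stats::var)
  n_hvg <- min(n_hvg, length(shared))
  hvg <- shared[order(-v, seq_along(v))[seq_len(n_hvg)]]
  n_pcs <- min(n_pcs, n_cells(reference) - 1L, length(hvg))
  pca <- fit_pca(reference, n_components = n_pcs, gene_subset = hvg,
                 scale. = scale.)
  if (is.null(embedding)) {
    embedding <- pca$scores[, seq_len(min(2, ncol(pca$scores))), drop = FALSE]
  } else {
    embedding <- as.matrix(embedding)
    if (nrow(embedding) != n_cells(reference))
      stop("embedding must have one row per reference cell")
  }
  rownames(embedding) <- reference$cell_ids
  if (!is.null(ref_clusters))
    ref_clusters <- as_cluster_factor(ref_clusters, reference$cell_ids)
  structure(list(pca = pca, ref_scores = pca$scores, embedding = embedding,
                 ref_clusters = ref_clusters, ref_ids = reference$cell_ids,
                 hvg = hvg),
            class = "reference_map")
}

#' Project query cells onto a reference map via k-nearest-neighbor anchors
#'
#' Query cells are transformed with the reference's gene subset, centering,
#' scaling and PC loadings, then each query cell's k nearest reference cells
#' (exact Euclidean search in PC space, default k = 5) are taken as its
#' anchors. Ties are broken by reference cell order, so the result is
#' deterministic and invariant to query cell order.
#'
#' @param map A \code{\link{fit_reference}} result.
#' @param query A normalized \code{\link{cell_dataset}} containing the map's
#'   HVGs.
#' @param k Number of anchors per query cell.
#' @return A \code{projection_result}: list with \code{anchors} (query x k
#'   matrix of reference cell ids), \code{anchor_index}, \code{distances}
#'   (query x k, non-decreasing along each row), \code{query_ids}.
#' @export
project_query <- function(map, query, k = 5) {
  if (k > length(map$ref_ids))
    stop("k exceeds the number of reference cells")
  if (n_cells(query) == 0)
    return(structure(list(anchors = matrix(character(), 0, k),
                          anchor_index = matrix(integer(), 0, k),
                          distances = matrix(numeric(), 0, k),
                          query_ids = character()),
                     class = "projection_result"))
  q_scores <- pca_transform(map$pca, query)
  nn <- knn_search(map$ref_scores, q_scores, k)
  anchors <- matrix(map$ref_ids[nn$index], nrow(nn$index), k)
  rownames(anchors) <- rownames(nn$dist) <- query$cell_ids
  structure(list(anchors = anchors, anchor_index = nn$index,
                 distances = nn$dist, query_ids = query$cell_ids),
            class = "projection_result")
}

#' Kernel density of projection anchors on the reference embedding
#'
#' Renders a projection as a Gaussian kernel density estimate over the
#' anchors' embedding coordinates, anchors counted with multiplicity.
#' Per-axis bandwidth follows Scott's rule (sd * n^(-1/6)); the grid covers
#' the reference embedding extent padded by 4 bandwidths and the density is
#' normalized so its Riemann sum over the grid is exactly 1.
#'
#' @param map A \code{\link{reference_map}}.
#' @param result A \code{\link{project_query}} result with >= 1 anchor.
#' @param grid_size Grid points per axis (default 200).
#' @param bandwidth Optional length-2 numeric bandwidth override.
#' @return List with \code{x}, \code{y} (grid coordinates), \code{z}
#'   (grid_size x grid_size density), \code{bandwidth}.
#' @export
anchor_density <- function(map, result, grid_size = 200, bandwidth = NULL) {
  idx <- as.vector(result$anchor_index)
  if (!length(idx)) stop("projection has no anchors")
  pts <- map$embedding[idx, , drop = FALSE]
  n <- nrow(pts)
  if (is.null(bandwidth)) {
    bandwidth <- vapply(1:2, function(d) {
      s <- stats::sd(pts[, d])
      if (is.na(s) || s == 0) s <- 1e-3
      s * n^(-1 / 6)
    }, numeric(1))
  }
  ext <- apply(map$embedding, 2, range)
  lo <- pmin(ext[1, ], apply(pts, 2, min)) - 4 * bandwidth
  hi <- pmax(ext[2, ], apply(pts, 2, max)) + 4 * bandwidth
  gx <- seq(lo[1], hi[1], length.out = grid_size)
  gy <- seq(lo[2], hi[2], length.out = grid_size)
  # separable Gaussian kernel: z = (1/n) * Kx %*% t(Ky) summed over anchors
  kx <- vapply(pts[, 1], function(m) stats::dnorm(gx, m, bandwidth[1]),
               numeric(grid_size))
  ky <- vapply(pts[, 2], function(m) stats::dnorm(gy, m, bandwidth[2]),
               numeric(grid_size))
  z <- tcrossprod(kx, ky) / n
  dx <- gx[2] - gx[1]
  dy <- gy[2] - gy[1]
  z <- z / (sum(z) * dx * dy)
  list(x = gx, y = gy, z = z, bandwidth = bandwidth)
}

#' Purity of anchors with respect to reference cluster labels
#'
#' Fraction of all anchors (with multiplicity) whose reference cluster equals
#' the supplied per-query expected cluster. Used to validate projections of
#' cells with known cluster of origin.
#'
#' @param map A \code{\link{reference_map}} with \code{ref_clusters} set.
#' @param result A \code{\link{project_query}} result.
#' @param expected Factor/character of expected clusters, one per query cell.
#' @return Fraction in [0, 1].
#' @export
anchor_purity <- function(map, result, expected) {
  if (is.null(map$ref_clusters))
    stop("reference map has no cluster labels")
  anchor_cl <- matrix(as.character(map$ref_clusters)[result$anchor_index],
                      nrow(result$anchor_index))
  mean(anchor_cl == as.character(expected)[row(anchor_cl)])
}
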