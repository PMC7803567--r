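make_norm <- function(mat, ...) {
  ds <- make_dataset(mat, ...)
  normalize_log(ds)
}

test_that("PCA component variances match a dense covariance eigendecomposition", {
  set.seed(7)
  counts <- matrix(rpois(50 * 20, 5), 50, 20)
  ds <- make_norm(counts)
  p <- fit_pca(ds, n_components = 20, scale. = FALSE, clip = 1e6)
  X <- as.matrix(ds$normalized)
  ev <- eigen(stats::cov(X), symmetric = TRUE)$values
  expect_equal(p$sdev^2, ev[1:20], tolerance = 1e-8)
  expect_true(all(diff(p$sdev) <= 1e-10))
  # loadings orthonormal, scores reconstruct the centered data
  expect_equal(crossprod(p$loadings), diag(20), tolerance = 1e-8,
               ignore_attr = TRUE)
  Xc <- scale(X, center = p$center, scale = FALSE)
  expect_equal(unname(p$scores %*% t(p$loadings)), unname(Xc),
               tolerance = 1e-8, ignore_attr = TRUE)
})

test_that("rank-deficient data has no variance beyond its true rank", {
  set.seed(1)
  f1 <- rnorm(40); f2 <- rnorm(40)
  l1 <- runif(15); l2 <- runif(15)
  X <- round(20 * abs(outer(f1, l1) + outer(f2, l2)))
  ds <- make_norm(X)
  # rank <= 2 after normalization is not exact, so test on the raw structure
  ds$normalized <- Matrix::Matrix(outer(f1, l1) + outer(f2, l2), sparse = TRUE)
  p <- fit_pca(ds, n_components = 10, scale. = FALSE, clip = 1e6)
  expect_lt(p$sdev[3] / p$sdev[1], 1e-8)
  expect_error(fit_pca(ds, n_components = 100), "n_components")
})

test_that("graph clustering recovers well-separated planted clusters", {
  skip_if_not_installed("mclust")
  g <- generate_sc_dataset(sim_spec(n_clusters = 3, cells_per_cluster = 100,
                                    n_genes = 400, n_markers_per_cluster = 20,
                                    marker_fold_change = 6, seed = 17))
  ds <- normalize_log(g$dataset)
  p <- fit_pca(ds, 10)
  cl <- cluster_cells(p$scores, seed = 5)
  expect_gte(mclust::adjustedRandIndex(cl$cluster, g$truth$cluster), 0.9)
  # determinism under identical seed
  cl2 <- cluster_cells(p$scores, seed = 5)
  expect_identical(cl$cluster, cl2$cluster)
})

test_that("identical cells form a single cluster and tiny inputs error", {
  X <- matrix(5, 60, 20)
  ds <- make_norm(X)
  p <- fit_pca(ds, 2, scale. = FALSE)
  cl <- cluster_cells(p$scores, k_neighbors = 10, seed = 1)
  expect_equal(nlevels(droplevels(cl$cluster)), 1)
  expect_error(cluster_cells(p$scores[1:5, , drop = FALSE], k_neighbors = 10),
               "k_neighbors")
})

test_that("rank-sum marker p equals exhaustive 5v5 enumeration on a toy", {
  x <- c(1.3, 2.7, 0.2, 4.1, 3.3)
  y <- c(5.0, 6.2, 4.4, 7.1, 2.9)
  counts <- matrix(1, 10, 3)
  ds <- make_dataset(counts)
  ds$normalized <- Matrix::Matrix(cbind(c(x, y), seq(0.1, 1, 0.1),
                                        seq(1, 0.1, -0.1)), sparse = FALSE)
  dimnames(ds$normalized) <- dimnames(ds$counts)
  cl <- factor(rep(c("A", "B"), each = 5))
  names(cl) <- ds$cell_ids
  mk <- find_markers(ds, cl, target = "A", min_pct = 0)
  expect_equal(mk$p_value[mk$gene == "G001"], oracle_rank_sum_p(x, y),
               tolerance = 1e-12)
})

test_that("planted markers are detected with large fold change and low FDR", {
  g <- generate_sc_dataset(sim_spec(n_clusters = 2, cells_per_cluster = 100,
                                    n_genes = 400, n_markers_per_cluster = 20,
                                    marker_fold_change = 4, seed = 23))
  ds <- normalize_log(g$dataset)
  mk <- find_markers(ds, g$truth$cluster, target = "C1")
  planted <- mk[mk$gene %in% g$truth$marker_genes$C1, ]
  expect_gte(mean(planted$fdr < 0.05 & planted$log2_fold_change > 1), 0.9)
  # BH monotonicity: fdr >= p elementwise and step-up shape on sorted p
  expect_true(all(mk$fdr >= mk$p_value - 1e-12))
  expect_equal(mk$fdr, p.adjust(mk$p_value, "BH"))
})

test_that("marker test is calibrated on label-permuted null data", {
  g <- generate_sc_dataset(sim_spec(n_clusters = 2, cells_per_cluster = 100,
                                    n_genes = 500, n_markers_per_cluster = 0,
                                    marker_fold_change = 1, base_mean = 2,
                                    mito_gene_count = 0, seed = 29))
  ds <- normalize_log(g$dataset)
  mk <- find_markers(ds, g$truth$cluster, target = "C1", min_pct = 0)
  frac <- mean(mk$p_value < 0.05)
  expect_gt(frac, 0.02)
  expect_lt(frac, 0.08)
})

test_that("module scores are zero on constant data and planted-set specific", {
  const <- make_dataset(matrix(3, 50, 40))
  const$normalized <- const$counts
  sc <- module_score(const, c("G001", "G005"), seed = 1)
  expect_equal(unname(sc), rep(0, 50), tolerance = 1e-12)

  g <- generate_sc_dataset(sim_spec(n_clusters = 2, cells_per_cluster = 80,
                                    n_genes = 300, n_markers_per_cluster = 15,
                                    marker_fold_change = 4, seed = 31))
  ds <- normalize_log(g$dataset)
  sc <- module_score(ds, g$truth$marker_genes$C1, seed = 2)
  in_c1 <- g$truth$cluster == "C1"
  expect_gt(mean(sc[in_c1]), mean(sc[!in_c1]))
  expect_identical(sc, module_score(ds, g$truth$marker_genes$C1, seed = 2))
  expect_error(module_score(ds, c("NOPE1", "NOPE2")), "intersect")
})

test_that("cell-cycle scoring assigns planted G2M cells and defaults to G1", {
  cc <- cc_genes()
  g2m_cells <- 1:60
  g <- generate_sc_dataset(
    sim_spec(n_clusters = 1, cells_per_cluster = 150, n_genes = 300,
             n_markers_per_cluster = 0, base_mean = 2, seed = 37),
    programs = list(list(genes = cc$g2m, cells = g2m_cells, fold = 5),
                    list(genes = cc$s, cells = integer(), fold = 1)))
  ds <- normalize_log(g$dataset)
  res <- cell_cycle_score(ds)
  expect_gte(mean(res$phase[g2m_cells] == "G2M"), 0.9)
  # phases partition the cells
  expect_equal(sum(table(res$phase)), n_cells(ds))

  const <- make_dataset(matrix(2, 20, length(c(cc$s, cc$g2m))),
                        genes = c(cc$s, cc$g2m))
  const$normalized <- const$counts
  res0 <- cell_cycle_score(const)
  expect_true(all(res0$phase == "G1"))
})
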