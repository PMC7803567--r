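test_that("extracted signatures recover the planted marker set", {
  g <- generate_sc_dataset(sim_spec(n_clusters = 2, cells_per_cluster = 100,
                                    n_genes = 400, n_markers_per_cluster = 20,
                                    marker_fold_change = 4, seed = 51))
  ds <- normalize_log(g$dataset)
  mk <- find_markers(ds, g$truth$cluster, target = "C1")
  sig <- extract_signature(ds, g$truth$cluster, "C1", mk,
                           top_n = 20)
  expect_gte(mean(sig$gene %in% g$truth$marker_genes$C1), 0.9)
  # values are in-cluster means of normalized expression
  in_c1 <- which(g$truth$cluster == "C1")
  expect_equal(unname(sig$value),
               unname(Matrix::colMeans(ds$normalized[in_c1, sig$gene])))
  # top_n beyond availability is clamped; identical inputs reproduce exactly
  big <- extract_signature(ds, g$truth$cluster, "C1", mk, top_n = 1e4)
  expect_lte(length(big$gene), nrow(mk))
  expect_identical(sig, extract_signature(ds, g$truth$cluster, "C1", mk,
                                          top_n = 20))
  # an impossible significance gate errors with guidance
  expect_error(extract_signature(ds, g$truth$cluster, "C1", mk,
                                 max_fdr = 1e-300, min_fc = 1e6),
               "no significant markers")
})

test_that("cohort scoring is the Pearson correlation over shared genes", {
  sig <- signature_profile(c("A", "B", "C"), c(1, 2, 3))
  expr <- cbind(same = c(1, 2, 3), flipped = c(3, 2, 1),
                swapped = c(1, 3, 2), flat = c(2, 2, 2))
  rownames(expr) <- c("A", "B", "C")
  cohort <- bulk_cohort(expr, c("responder", "responder", "nonresponder",
                                "nonresponder"))
  expect_warning(sc <- score_cohort(sig, cohort), "zero-variance")
  expect_equal(unname(sc[1:3]), c(1, -1, 0.5))
  expect_true(is.na(sc[4]))
  expect_error(score_cohort(signature_profile(c("X", "Y", "Z"), 1:3), cohort),
               "fewer than 3")
})

test_that("group comparison matches a label-permutation oracle and is calibrated", {
  set.seed(61)
  x <- rnorm(10, 0.35); y <- rnorm(10, 0)
  scores <- c(x, y)
  labels <- rep(c("nonresponder", "responder"), each = 10)
  res <- compare_groups(scores, labels)
  # permutation null of the Welch t statistic (10,000 shuffles)
  tobs <- abs(res$t)
  perm <- replicate(10000, {
    sh <- sample(scores)
    abs(t.test(sh[1:10], sh[11:20])$statistic)
  })
  expect_lt(abs(res$p_value - mean(perm >= tobs)), 0.03)

  ident <- compare_groups(rep(c(1, 2, 3, 4), 2),
                          rep(c("nonresponder", "responder"), each = 4))
  expect_equal(ident$t, 0)
  expect_equal(ident$p_value, 1)

  # type-I error calibration under the null
  set.seed(62)
  pvals <- replicate(400, compare_groups(rnorm(20), labels)$p_value)
  expect_gt(mean(pvals < 0.05), 0.02)
  expect_lt(mean(pvals < 0.05), 0.08)
})

test_that("AUC equals the exhaustive pairwise count and honors its invariants", {
  lab4 <- c("nonresponder", "nonresponder", "responder", "responder")
  r <- roc_auc(c(0.9, 0.6, 0.8, 0.7), lab4)
  expect_equal(r$auc, 0.5)
  expect_equal(roc_auc(c(5, 6, 1, 2), lab4)$auc, 1.0)

  set.seed(71)
  for (i in 1:25) {
    pos <- rnorm(20); neg <- rnorm(20, -0.5)
    scores <- c(pos, neg)
    labels <- rep(c("nonresponder", "responder"), each = 20)
    r <- roc_auc(scores, labels)
    expect_equal(r$auc, oracle_auc_pairs(pos, neg), tolerance = 1e-12)
    # monotone-transform invariance and complement symmetry
    expect_equal(roc_auc(exp(scores), labels)$auc, r$auc)
    expect_equal(roc_auc(-scores, labels)$auc, 1 - r$auc)
    # CI brackets the point estimate; ROC curve is monotone
    expect_gte(r$auc, r$auc_ci_low)
    expect_lte(r$auc, r$auc_ci_high)
    expect_true(all(diff(r$sensitivity) >= -1e-12))
    expect_true(all(diff(r$specificity) <= 1e-12))
  }
  expect_error(roc_auc(1:4, rep("responder", 4)), "both classes")
})

test_that("AUC and DeLong interval agree with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(73)
  scores <- c(rnorm(30, 1), rnorm(40))
  labels <- rep(c("nonresponder", "responder"), c(30, 40))
  r <- roc_auc(scores, labels)
  ref <- pROC::roc(response = labels, predictor = scores,
                   levels = c("responder", "nonresponder"),
                   direction = "<", quiet = TRUE)
  ci <- as.numeric(pROC::ci.auc(ref, method = "delong"))
  expect_equal(r$auc, as.numeric(pROC::auc(ref)), tolerance = 1e-10)
  expect_equal(c(r$auc_ci_low, r$auc_ci_high), ci[c(1, 3)], tolerance = 1e-6)
})

test_that("combined signatures behave as documented and do not lose signal", {
  b <- generate_bulk_cohort(cohort_spec(n_positive = 40, n_negative = 40,
                                        effect_size_d = 1.5, seed = 81))
  sig <- b$signature
  same <- combine_signatures(list(sig, sig), b$cohort,
                             method = "mean_correlation")
  expect_equal(same, score_cohort(sig, b$cohort))
  expect_equal(combine_signatures(list(sig, sig), b$cohort, method = "union"),
               score_cohort(sig, b$cohort))

  # mean_correlation is the arithmetic mean of per-signature scores
  sig2 <- signature_profile(rownames(b$cohort$expression)[201:260],
                            rnorm(60), "noise")
  comb <- combine_signatures(list(sig, sig2), b$cohort)
  expect_equal(comb, (score_cohort(sig, b$cohort) +
                        score_cohort(sig2, b$cohort)) / 2)
  expect_error(combine_signatures(list(sig), b$cohort), "at least 2")
  expect_error(combine_signatures(list(sig, sig2), b$cohort, method = "nope"))
})

test_that("combining two informative partially-overlapping signatures preserves AUC", {
  # two overlapping halves of one planted 75-gene template: each half is an
  # informative signature; combining them should not lose discrimination
  deltas <- vapply(1:10, function(s) {
    b1 <- generate_bulk_cohort(cohort_spec(n_positive = 50, n_negative = 50,
                                           effect_size_d = 1.5,
                                           signature_size = 75, n_genes = 500,
                                           seed = 900 + s))
    parent <- b1$signature
    sig1 <- signature_profile(parent$gene[1:50], parent$value[1:50], "half1")
    sig2 <- signature_profile(parent$gene[26:75], parent$value[26:75],
                              "half2")
    auc1 <- roc_auc(score_cohort(sig1, b1$cohort), b1$cohort$labels)$auc
    auc2 <- roc_auc(score_cohort(sig2, b1$cohort), b1$cohort$labels)$auc
    comb <- combine_signatures(list(sig1, sig2), b1$cohort)
    roc_auc(comb, b1$cohort$labels)$auc - max(auc1, auc2)
  }, numeric(1))
  expect_gte(mean(deltas), -0.02)
})

test_that("signature TSV round trip and probe collapse work", {
  sig <- signature_profile(c("g1", "g2"), c(0.5, 1.5), "CluX")
  path <- withr::local_tempfile(fileext = ".tsv")
  write_signature(sig, path)
  back <- read_signature(path, "CluX")
  expect_equal(back$gene, sig$gene)
  expect_equal(back$value, sig$value)

  probes <- rbind(p1 = c(1, 2), p2 = c(5, 6), p3 = c(2, 2))
  collapsed <- collapse_probes(probes, c("GENE1", "GENE1", "GENE2"))
  expect_equal(collapsed["GENE1", ], c(5, 6), ignore_attr = TRUE)
  expect_equal(collapsed["GENE2", ], c(2, 2), ignore_attr = TRUE)
})
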