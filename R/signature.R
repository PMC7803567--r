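#' Construct a gene-signature profile
#'
#' An ordered gene list with one representative expression value per gene
#' (typically the cluster mean of log-normalized expression) -- the template
#' against which bulk patient profiles are correlated.
#'
#' @param genes Character vector of unique gene names.
#' @param values Numeric vector, one value per gene.
#' @param source_cluster Label of the cluster the signature summarizes.
#' @return A \code{signature_profile} list.
#' @export
signature_profile <- function(genes, values, source_cluster = NA_character_) {
  genes <- as.character(genes)
  values <- as.numeric(values)
  if (length(genes) != length(values))
    stop("genes and values must have the same length")
  if (anyDuplicated(genes)) stop("signature genes must be unique")
  structure(list(gene = genes, value = values,
                 source_cluster = source_cluster),
            class = "signature_profile")
}

#' Construct a bulk expression cohort
#'
#' @param expression Gene x patient numeric matrix, log2 scale, with unique
#'   row (gene) and column (patient) names.
#' @param labels Response label per patient: factor/character with values
#'   "responder"/"nonresponder" (or named, matched to patients).
#' @return A \code{bulk_cohort} list.
#' @export
bulk_cohort <- function(expression, labels) {
  expression <- as.matrix(expression)
  if (is.null(rownames(expression)) || is.null(colnames(expression)))
    stop("expression matrix needs gene rownames and patient colnames")
  if (anyDuplicated(rownames(expression))) stop("gene names must be unique")
  if (!is.null(names(labels))) labels <- labels[colnames(expression)]
  if (length(labels) != ncol(expression))
    stop("one label per patient required")
  labels <- factor(as.character(labels),
                   levels = c("responder", "nonresponder"))
  if (anyNA(labels)) stop("labels must be 'responder' or 'nonresponder'")
  names(labels) <- colnames(expression)
  structure(list(expression = expression, labels = labels),
            class = "bulk_cohort")
}

#' Extract a cluster signature from marker results
#'
#' Takes a cluster's significant positive markers (BH FDR below
#' \code{max_fdr} and linear fold change above \code{min_fc}), orders them
#' by FDR then fold change, keeps the top \code{top_n} (clamped to
#' availability), and records each gene's mean normalized expression within
#' the cluster as the signature value.
#'
#' @param dataset A normalized \code{\link{cell_dataset}}.
#' @param clusters Cluster labels (factor named by cell id, or a
#'   \code{cluster_assignment}).
#' @param cluster_label The cluster to summarize.
#' @param markers MarkerTable from \code{\link{find_markers}} /
#'   \code{\link{find_all_markers}}.
#' @param top_n Signature size (default 50).
#' @param max_fdr,min_fc Marker significance gates (defaults: FDR < 0.05,
#'   fold change > 2).
#' @return A \code{\link{signature_profile}}.
#' @export
extract_signature <- function(dataset, clusters, cluster_label, markers,
                              top_n = 50, max_fdr = 0.05, min_fc = 2) {
  clusters <- as_cluster_factor(clusters, dataset$cell_ids)
  in_cells <- which(clusters == cluster_label)
  if (length(in_cells) < 3)
    stop("cluster ", cluster_label, " has fewer than 3 cells")
  mk <- markers[markers$cluster == as.character(cluster_label) &
                  markers$fdr < max_fdr &
                  markers$log2_fold_change > log2(min_fc), , drop = FALSE]
  if (!nrow(mk))
    stop("no significant markers for cluster ", cluster_label,
         "; relax max_fdr/min_fc or re-run find_markers with more cells")
  mk <- mk[order(mk$fdr, -mk$log2_fold_change), , drop = FALSE]
  genes <- utils::head(mk$gene, top_n)
  vals <- Matrix::colMeans(
    norm_matrix(dataset)[in_cells, genes, drop = FALSE])
  signature_profile(genes, as.numeric(vals),
                    source_cluster = as.character(cluster_label))
}

#' Score bulk patients by Pearson correlation with a signature
#'
#' For every patient, the Pearson correlation between the signature values
#' and the patient's log2 expression over the genes shared between signature
#' and cohort. Patients with zero expression variance over the shared genes
#' get \code{NA} with a warning.
#'
#' @param signature A \code{\link{signature_profile}}.
#' @param cohort A \code{\link{bulk_cohort}}.
#' @return Numeric correlation per patient, named.
#' @export
score_cohort <- function(signature, cohort) {
  shared <- intersect(signature$gene, rownames(cohort$expression))
  if (length(shared) < 3)
    stop("signature and cohort share fewer than 3 genes")
  s <- signature$value[match(shared, signature$gene)]
  if (stats::sd(s) == 0) stop("signature values are constant on shared genes")
  E <- cohort$expression[shared, , drop = FALSE]
  scores <- apply(E, 2, function(x)
    if (stats::sd(x) == 0) NA_real_ else stats::cor(x, s))
  if (anyNA(scores))
    warning(sum(is.na(scores)),
            " patient(s) with zero-variance profiles scored as NA")
  scores
}

#' Compare correlation scores between response classes (Welch t-test)
#'
#' @param scores Numeric score per patient (named or aligned to labels).
#' @param labels responder/nonresponder factor per patient.
#' @return List with \code{t}, \code{p_value}, \code{df},
#'   \code{mean_nonresponder}, \code{mean_responder}.
#' @export
compare_groups <- function(scores, labels) {
  labels <- align_labels(scores, labels)
  ok <- !is.na(scores)
  scores <- scores[ok]; labels <- labels[ok]
  if (min(table(labels)) < 2)
    stop("need at least 2 scored patients per class")
  tt <- stats::t.test(scores[labels == "nonresponder"],
                      scores[labels == "responder"])
  list(t = unname(tt$statistic), p_value = tt$p.value,
       df = unname(tt$parameter),
       mean_nonresponder = mean(scores[labels == "nonresponder"]),
       mean_responder = mean(scores[labels == "responder"]))
}

align_labels <- function(scores, labels) {
  if (inherits(labels, "bulk_cohort")) labels <- labels$labels
  if (!is.null(names(labels)) && !is.null(names(scores)))
    labels <- labels[names(scores)]
  labels <- factor(as.character(labels),
                   levels = c("responder", "nonresponder"))
  if (length(labels) != length(scores) || anyNA(labels))
    stop("labels must align with scores and be responder/nonresponder")
  labels
}

#' ROC curve and AUC for non-response prediction
#'
#' Higher scores predict the positive class (non-responder). The AUC is the
#' Mann-Whitney U probability (ties counted 1/2); its confidence interval is
#' computed by the DeLong method. Optional stratified-bootstrap bands give
#' the sensitivity interval at each specificity.
#'
#' @param scores Numeric score per patient; \code{NA} scores are dropped.
#' @param labels responder/nonresponder per patient (nonresponder positive).
#' @param conf_level Confidence level for the AUC interval.
#' @param boot_bands Compute bootstrap sensitivity bands.
#' @param n_boot Stratified bootstrap resamples for the bands.
#' @param seed Seed for the bootstrap.
#' @return A \code{roc_result}: list with \code{thresholds},
#'   \code{sensitivity}, \code{specificity}, \code{auc}, \code{auc_ci_low},
#'   \code{auc_ci_high}, \code{n_pos}, \code{n_neg}, and (optionally)
#'   \code{bands} (specificity grid with sensitivity quantiles).
#' @export
roc_auc <- function(scores, labels, conf_level = 0.95, boot_bands = FALSE,
                    n_boot = 2000, seed = 0L) {
  labels <- align_labels(scores, labels)
  ok <- !is.na(scores)
  scores <- scores[ok]; labels <- labels[ok]
  pos <- scores[labels == "nonresponder"]
  neg <- scores[labels == "responder"]
  if (!length(pos) || !length(neg))
    stop("both classes must be present")
  auc <- auc_mw(pos, neg)
  ci <- delong_ci(pos, neg, conf_level)
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  sens <- vapply(thr, function(t) mean(pos >= t), numeric(1))
  spec <- vapply(thr, function(t) mean(neg < t), numeric(1))
  out <- list(thresholds = thr, sensitivity = sens, specificity = spec,
              auc = auc, auc_ci_low = ci[1], auc_ci_high = ci[2],
              n_pos = length(pos), n_neg = length(neg))
  if (boot_bands) {
    spec_grid <- seq(0, 1, length.out = 101)
    sens_at <- function(p, n) {
      t2 <- c(Inf, sort(unique(c(p, n)), decreasing = TRUE))
      se <- vapply(t2, function(t) mean(p >= t), numeric(1))
      sp <- vapply(t2, function(t) mean(n < t), numeric(1))
      # best attainable sensitivity at each specificity level
      vapply(spec_grid, function(s) max(se[sp >= s]), numeric(1))
    }
    bands <- with_seed(seed, {
      sims <- replicate(n_boot, sens_at(sample(pos, replace = TRUE),
                                        sample(neg, replace = TRUE)))
      t(apply(sims, 1, stats::quantile,
              probs = c((1 - conf_level) / 2, 1 - (1 - conf_level) / 2)))
    })
    out$bands <- data.frame(specificity = spec_grid,
                            sens_low = bands[, 1], sens_high = bands[, 2])
  }
  structure(out, class = "roc_result")
}

# AUC as the Mann-Whitney probability via midranks (ties counted 1/2).
auc_mw <- function(pos, neg) {
  r <- rank(c(pos, neg))
  np <- length(pos); nn <- length(neg)
  (sum(r[seq_len(np)]) - np * (np + 1) / 2) / (np * nn)
}

# DeLong variance of the AUC from placement values.
delong_ci <- function(pos, neg, conf_level = 0.95) {
  np <- length(pos); nn <- length(neg)
  v10 <- vapply(pos, function(p)
    (sum(p > neg) + 0.5 * sum(p == neg)) / nn, numeric(1))
  v01 <- vapply(neg, function(n)
    (sum(pos > n) + 0.5 * sum(pos == n)) / np, numeric(1))
  se <- sqrt(stats::var(v10) / np + stats::var(v01) / nn)
  if (is.na(se)) se <- 0
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  auc <- auc_mw(pos, neg)
  c(max(0, auc - z * se), min(1, auc + z * se))
}

#' @method print roc_result
#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("ROC: AUC = %.3f (%.0f%% CI %.3f-%.3f), %d nonresponders vs %d responders\n",
              x$auc, 95, x$auc_ci_low, x$auc_ci_high, x$n_pos, x$n_neg))
  invisible(x)
}

#' Combine several cluster signatures into one patient score
#'
#' \code{"mean_correlation"} (default) averages the per-signature Pearson
#' scores; \code{"union"} concatenates the signatures into one gene list
#' (values of duplicated genes averaged) and scores that single profile.
#'
#' @param signatures List of >= 2 \code{\link{signature_profile}} objects.
#' @param cohort A \code{\link{bulk_cohort}}.
#' @param method "mean_correlation" or "union".
#' @return Numeric score per patient, named.
#' @export
combine_signatures <- function(signatures, cohort,
                               method = c("mean_correlation", "union")) {
  method <- match.arg(method)
  if (length(signatures) < 2)
    stop("need at least 2 signatures to combine")
  if (method == "mean_correlation") {
    mat <- vapply(signatures, score_cohort, cohort = cohort,
                  numeric(ncol(cohort$expression)))
    return(rowMeans(mat))
  }
  genes <- unlist(lapply(signatures, `[[`, "gene"))
  values <- unlist(lapply(signatures, `[[`, "value"))
  merged <- tapply(values, genes, mean)
  # keep first-appearance gene order
  ord <- unique(genes)
  score_cohort(signature_profile(ord, as.numeric(merged[ord]),
                                 source_cluster = "combined"),
               cohort)
}

#' Collapse probe-level expression to gene level by maximum value
#'
#' Utility for microarray cohorts where several probes map to one gene:
#' keeps, per gene, the probe with the highest mean expression.
#'
#' @param expression Probe x sample matrix.
#' @param probe_genes Gene symbol per probe (same length as
#'   \code{nrow(expression)}).
#' @return Gene x sample matrix.
#' @export
collapse_probes <- function(expression, probe_genes) {
  expression <- as.matrix(expression)
  stopifnot(length(probe_genes) == nrow(expression))
  keep <- tapply(seq_len(nrow(expression)), probe_genes, function(ix)
    ix[which.max(rowMeans(expression[ix, , drop = FALSE]))])
  out <- expression[as.integer(keep), , drop = FALSE]
  rownames(out) <- names(keep)
  out
}

#' Write / read a signature as two-column TSV (gene, value)
#'
#' @param signature A \code{\link{signature_profile}}.
#' @param path TSV file path.
#' @return \code{path} invisibly (write); a \code{signature_profile} (read).
#' @export
write_signature <- function(signature, path) {
  utils::write.table(data.frame(gene = signature$gene,
                                value = signature$value),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_signature
#' @param source_cluster Cluster label to attach on read.
#' @export
read_signature <- function(path, source_cluster = NA_character_) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  signature_profile(tab$gene, tab$value, source_cluster)
}
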