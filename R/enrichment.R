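#' Fisher's exact test on a 2x2 contingency table
#'
#' Two-sided exact p by the classic convention: the sum of hypergeometric
#' probabilities of all tables (with the observed margins) whose point
#' probability does not exceed the observed table's. The odds ratio is the
#' sample cross-product \code{(a*d)/(b*c)}; the Haldane-corrected version
#' adds 0.5 to every cell and is always finite, making \code{log10} odds
#' ratios comparable across tables with zero cells.
#'
#' @param table A 2x2 matrix \code{rbind(c(a, b), c(c, d))}, or the four
#'   counts given separately. Layout for enrichment: rows = in/out of the
#'   cluster, columns = in/out of the sample.
#' @param a,b,c,d Alternative scalar interface.
#' @return List with \code{p_value}, \code{odds_ratio} (cross-product, may
#'   be Inf/NaN at zeros), \code{odds_ratio_haldane},
#'   \code{log10_odds_ratio} (of the Haldane-corrected OR).
#' @export
fisher_2x2 <- function(table = NULL, a = NULL, b = NULL, c = NULL, d = NULL) {
  if (is.null(table)) table <- rbind(c(a, b), c(c, d))
  table <- matrix(as.numeric(table), 2, 2)
  if (any(table < 0) || any(table != round(table)))
    stop("table entries must be non-negative integers")
  if (sum(table) == 0) stop("all-zero table")
  p <- stats::fisher.test(table)$p.value
  or_raw <- (table[1, 1] * table[2, 2]) / (table[1, 2] * table[2, 1])
  th <- table + 0.5
  or_h <- (th[1, 1] * th[2, 2]) / (th[1, 2] * th[2, 1])
  list(p_value = p, odds_ratio = or_raw, odds_ratio_haldane = or_h,
       log10_odds_ratio = log10(or_h))
}

#' Enrichment of each sample within each cluster (Fisher exact)
#'
#' For every (cluster, sample) pair, builds the 2x2 membership table
#' (cell in cluster x cell from sample vs the rest) and applies
#' \code{\link{fisher_2x2}}; p-values are BH-corrected across all pairs.
#' The log10 Haldane-corrected odds ratio is the enrichment score.
#'
#' @param clusters Factor of cluster labels per cell.
#' @param sample_labels Factor of sample labels per cell (same length).
#' @return \code{data.frame} with columns \code{cluster}, \code{sample},
#'   \code{a} (cells in both), \code{log10_odds_ratio}, \code{p_value},
#'   \code{fdr}.
#' @export
cluster_sample_enrichment <- function(clusters, sample_labels) {
  clusters <- as.factor(clusters)
  sample_labels <- as.factor(sample_labels)
  stopifnot(length(clusters) == length(sample_labels))
  if (nlevels(clusters) < 2 || nlevels(sample_labels) < 2)
    stop("need at least 2 clusters and 2 samples")
  grid <- expand.grid(cluster = levels(clusters),
                      sample = levels(sample_labels),
                      stringsAsFactors = FALSE)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    in_c <- clusters == grid$cluster[i]
    in_s <- sample_labels == grid$sample[i]
    f <- fisher_2x2(rbind(c(sum(in_c & in_s), sum(in_c & !in_s)),
                          c(sum(!in_c & in_s), sum(!in_c & !in_s))))
    data.frame(cluster = grid$cluster[i], sample = grid$sample[i],
               a = sum(in_c & in_s),
               log10_odds_ratio = f$log10_odds_ratio,
               p_value = f$p_value, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$fdr <- stats::p.adjust(out$p_value, method = "BH")
  out
}

#' Percentage from a count and a denominator
#'
#' Reported to one decimal, the convention used for cell-fraction
#' statements (e.g. 429/863 -> 49.7).
#'
#' @param numerator,denominator Non-negative counts; denominator > 0.
#' @return Percentage rounded to one decimal.
#' @export
proportion <- function(numerator, denominator) {
  if (denominator <= 0) stop("denominator must be positive")
  round(100 * numerator / denominator, 1)
}

#' Bundled published-cohort cell counts
#'
#' Small table of printed cell counts from a published peripheral-blood CML
#' single-cell study, used by the worked examples: per-treatment-stage cell
#' counts with their printed total, the cell counts of the integrated
#' primitive-cluster/bone-marrow dataset, and the CD16+ monocyte counts in
#' the blast-crisis and healthy samples.
#'
#' @return \code{data.frame} with columns \code{group}, \code{subset},
#'   \code{count}.
#' @export
study_counts <- function() {
  path <- system.file("extdata", "study_counts.tsv", package = "cmlsig",
                      mustWork = TRUE)
  utils::read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
}
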