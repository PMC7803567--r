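# Independent brute-force oracles used across the suite. These deliberately
# re-derive each statistic from first principles, never through the package's
# own code paths.

# Two-sided Fisher p by full hypergeometric enumeration over all tables with
# the observed margins (point probabilities <= observed, with the standard
# relative tolerance for floating ties).
oracle_fisher_p <- function(tab) {
  m <- tab[1, 1] + tab[1, 2]   # row 1 total
  n <- tab[2, 1] + tab[2, 2]   # row 2 total
  k <- tab[1, 1] + tab[2, 1]   # column 1 total
  support <- max(0, k - n):min(k, m)
  probs <- dhyper(support, m, n, k)
  p_obs <- dhyper(tab[1, 1], m, n, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# AUC by exhaustive comparison of every (positive, negative) score pair,
# ties counted one half.
oracle_auc_pairs <- function(pos, neg) {
  cmp <- outer(pos, neg, function(p, n) (p > n) + 0.5 * (p == n))
  mean(cmp)
}

# Exact two-sided rank-sum p by enumerating all C(n1+n2, n1) group
# assignments of the pooled values (doubling convention, as the exact
# Wilcoxon test uses).
oracle_rank_sum_p <- function(x, y) {
  pooled <- c(x, y)
  n1 <- length(x)
  r <- rank(pooled)
  w_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  splits <- utils::combn(length(pooled), n1)
  w_all <- apply(splits, 2, function(ix) sum(r[ix]) - n1 * (n1 + 1) / 2)
  pl <- mean(w_all <= w_obs)
  pu <- mean(w_all >= w_obs)
  min(1, 2 * min(pl, pu))
}

# Brute-force k nearest neighbors of each query row among reference rows,
# with index tie-break.
oracle_knn <- function(ref, query, k) {
  t(apply(query, 1, function(q) {
    d <- sqrt(colSums((t(ref) - q)^2))
    order(d, seq_along(d))[seq_len(k)]
  }))
}

# A small normalized dataset with hand-set counts (dense input).
make_dataset <- function(counts, genes = NULL, cells = NULL, meta = NULL) {
  if (is.null(genes)) genes <- sprintf("G%03d", seq_len(ncol(counts)))
  if (is.null(cells)) cells <- sprintf("c%03d", seq_len(nrow(counts)))
  cell_dataset(counts, gene_names = genes, cell_ids = cells, cell_meta = meta)
}
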