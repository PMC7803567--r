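#' Specification for a synthetic single-cell dataset
#'
#' Describes a clustered UMI count matrix with planted cluster markers and
#' mitochondrial content, generated from a negative-binomial (gamma-Poisson)
#' count model. The generator is the ground-truth source for every
#' downstream test in the package.
#'
#' @param n_clusters Number of planted clusters.
#' @param cells_per_cluster Cells simulated per cluster.
#' @param n_genes Number of non-mitochondrial genes (mitochondrial genes,
#'   named with the reserved prefix \code{"MT-"}, are appended on top).
#' @param n_markers_per_cluster Genes planted as markers of each cluster.
#' @param marker_fold_change Linear fold change of a marker's mean in its own
#'   cluster relative to \code{base_mean}; must be >= 1.
#' @param base_mean Mean UMI count per gene outside marker/cluster structure.
#' @param mito_gene_count Number of mitochondrial genes.
#' @param mito_fraction_range Length-2 interval in [0,1]; each cell's expected
#'   mitochondrial UMI fraction is drawn uniformly from it.
#' @param dispersion Negative-binomial dispersion (\code{size = 1/dispersion});
#'   0.3 is a typical UMI over-dispersion.
#' @param seed Integer seed; identical spec + seed reproduces the matrix
#'   bit-exactly.
#'
#' @return A \code{sim_spec} list.
#' @export
sim_spec <- function(n_clusters = 3, cells_per_cluster = 100, n_genes = 1000,
                     n_markers_per_cluster = 20, marker_fold_change = 4,
                     base_mean = 1, mito_gene_count = 10,
                     mito_fraction_range = c(0.01, 0.04), dispersion = 0.3,
                     seed = 1L) {
  spec <- list(n_clusters = as.integer(n_clusters),
               cells_per_cluster = as.integer(cells_per_cluster),
               n_genes = as.integer(n_genes),
               n_markers_per_cluster = as.integer(n_markers_per_cluster),
               marker_fold_change = marker_fold_change,
               base_mean = base_mean,
               mito_gene_count = as.integer(mito_gene_count),
               mito_fraction_range = as.numeric(mito_fraction_range),
               dispersion = dispersion, seed = as.integer(seed))
  validate_sim_spec(spec)
  structure(spec, class = "sim_spec")
}

validate_sim_spec <- function(spec) {
  stopifnot(spec$n_clusters >= 1, spec$cells_per_cluster >= 1,
            spec$n_genes >= 1, spec$n_markers_per_cluster >= 0,
            spec$mito_gene_count >= 0, spec$dispersion > 0,
            spec$base_mean > 0,
            length(spec$mito_fraction_range) == 2,
            all(spec$mito_fraction_range >= 0),
            all(spec$mito_fraction_range < 1))
  if (spec$marker_fold_change < 1)
    stop("marker_fold_change must be >= 1")
  if (spec$n_markers_per_cluster * spec$n_clusters > spec$n_genes)
    stop("n_genes is too small for the requested number of markers ",
         "(need n_markers_per_cluster * n_clusters <= n_genes)")
  invisible(spec)
}

# Run code with a local RNG state so generators are deterministic without
# clobbering the caller's random stream.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Expected-count matrix (cells x genes) implied by a sim_spec, without noise.
# Returns list(mu, cluster, marker_genes, gene_names).
sim_mean_model <- function(spec) {
  n_cells <- spec$n_clusters * spec$cells_per_cluster
  cluster <- rep(seq_len(spec$n_clusters), each = spec$cells_per_cluster)
  genes <- sprintf("G%04d", seq_len(spec$n_genes))
  mu <- matrix(spec$base_mean, n_cells, spec$n_genes)
  marker_genes <- vector("list", spec$n_clusters)
  for (k in seq_len(spec$n_clusters)) {
    if (spec$n_markers_per_cluster == 0) { marker_genes[[k]] <- character(); next }
    idx <- (k - 1) * spec$n_markers_per_cluster +
      seq_len(spec$n_markers_per_cluster)
    marker_genes[[k]] <- genes[idx]
    mu[cluster == k, idx] <- spec$base_mean * spec$marker_fold_change
  }
  names(marker_genes) <- paste0("C", seq_len(spec$n_clusters))
  list(mu = mu, cluster = cluster, marker_genes = marker_genes,
       gene_names = genes)
}

# Draw NB counts for a mean matrix; vectorized over the full matrix.
nb_draw <- function(mu, dispersion) {
  cnt <- matrix(stats::rnbinom(length(mu), size = 1 / dispersion, mu = mu),
                nrow(mu), ncol(mu))
  cnt
}

#' Generate a clustered synthetic UMI dataset with known ground truth
#'
#' Counts follow a negative-binomial model: every gene has mean
#' \code{base_mean} except planted markers, whose mean is
#' \code{marker_fold_change * base_mean} inside their own cluster.
#' Mitochondrial genes (\code{"MT-"} prefix) are scaled per cell so the
#' expected mitochondrial UMI fraction equals a uniform draw from
#' \code{mito_fraction_range}. Optional expression programs (e.g. cell-cycle
#' gene sets) can be planted in designated cells.
#'
#' @param spec A \code{\link{sim_spec}}.
#' @param programs Optional list of programs, each a list with elements
#'   \code{genes} (character, appended as extra genes), \code{cells} (integer
#'   indices of cells carrying the program) and \code{fold} (mean fold
#'   elevation in those cells).
#'
#' @return A list with \code{dataset} (a \code{\link{cell_dataset}} whose
#'   \code{cell_meta$cluster} is the true cluster of origin) and \code{truth}
#'   (list: \code{cluster} factor, \code{marker_genes} per cluster,
#'   \code{mito_target} expected mito fraction per cell).
#' @export
generate_sc_dataset <- function(spec, programs = NULL) {
  validate_sim_spec(spec)
  with_seed(spec$seed, {
    mm <- sim_mean_model(spec)
    mu <- mm$mu
    genes <- mm$gene_names
    n_cells <- nrow(mu)
    for (p in programs) {
      stopifnot(is.character(p$genes), p$fold >= 1)
      extra <- matrix(spec$base_mean, n_cells, length(p$genes))
      extra[p$cells, ] <- spec$base_mean * p$fold
      mu <- cbind(mu, extra)
      genes <- c(genes, p$genes)
    }
    mito_target <- stats::runif(n_cells, spec$mito_fraction_range[1],
                                spec$mito_fraction_range[2])
    if (spec$mito_gene_count > 0) {
      nonmito_tot <- rowSums(mu)
      mito_mu <- (mito_target / (1 - mito_target)) * nonmito_tot /
        spec$mito_gene_count
      mu <- cbind(mu, matrix(rep(mito_mu, spec$mito_gene_count), n_cells))
      genes <- c(genes, sprintf("MT-%d", seq_len(spec$mito_gene_count)))
    }
    counts <- nb_draw(mu, spec$dispersion)
    cluster <- factor(paste0("C", mm$cluster))
    ds <- cell_dataset(
      counts,
      gene_names = genes,
      cell_ids = sprintf("cell%05d", seq_len(n_cells)),
      cell_meta = data.frame(cluster = cluster, sample = "synthetic",
                             stringsAsFactors = FALSE)
    )
    list(dataset = ds,
         truth = list(cluster = cluster, marker_genes = mm$marker_genes,
                      mito_target = mito_target))
  })
}

#' Generate a synthetic reference map plus query cells
#'
#' The reference is a clustered dataset drawn from \code{spec}; its 2-D
#' embedding is the first two PCs of the log-normalized counts, in which the
#' planted clusters separate. Query cells are fresh, independent draws from
#' the same per-cluster count model, so each query cell has a known cluster
#' of origin in the reference.
#'
#' @param spec A \code{\link{sim_spec}}.
#' @param n_query_per_cluster Query cells drawn per cluster (0 gives an empty
#'   query set).
#' @param n_pcs Components used for the reference embedding/PCA.
#'
#' @return List with \code{reference} (normalized \code{cell_dataset} with
#'   true \code{cluster} in \code{cell_meta}), \code{embedding} (reference
#'   cells x 2), \code{query} (normalized \code{cell_dataset}), and
#'   \code{truth} (\code{ref_cluster}, \code{query_cluster} factors).
#' @export
generate_reference_with_query <- function(spec, n_query_per_cluster = 20,
                                          n_pcs = 10) {
  validate_sim_spec(spec)
  n_query_per_cluster <- as.integer(n_query_per_cluster)
  stopifnot(n_query_per_cluster >= 0)
  with_seed(spec$seed, {
    mm <- sim_mean_model(spec)
    ref_counts <- nb_draw(mm$mu, spec$dispersion)
    ref <- cell_dataset(
      ref_counts, gene_names = mm$gene_names,
      cell_ids = sprintf("ref%05d", seq_len(nrow(ref_counts))),
      cell_meta = data.frame(cluster = factor(paste0("C", mm$cluster)))
    )
    ref <- normalize_log(ref)
    n_pcs <- min(n_pcs, n_cells(ref) - 1L, n_genes(ref))
    pca <- fit_pca(ref, n_components = n_pcs)
    embedding <- pca$scores[, 1:2, drop = FALSE]
    colnames(embedding) <- c("dim1", "dim2")

    q_cluster <- rep(seq_len(spec$n_clusters), each = n_query_per_cluster)
    q_mu <- mm$mu[!duplicated(mm$cluster), , drop = FALSE][q_cluster, ,
                                                           drop = FALSE]
    q_counts <- if (length(q_cluster)) nb_draw(q_mu, spec$dispersion) else
      matrix(0L, 0, spec$n_genes)
    query <- cell_dataset(
      q_counts, gene_names = mm$gene_names,
      cell_ids = if (length(q_cluster))
        sprintf("query%05d", seq_along(q_cluster)) else character(),
      cell_meta = data.frame(
        cluster = factor(paste0("C", q_cluster, recycle0 = TRUE),
                         levels = levels(ref$cell_meta$cluster)))
    )
    query <- normalize_log(query)
    list(reference = ref, embedding = embedding, query = query,
         truth = list(ref_cluster = ref$cell_meta$cluster,
                      query_cluster = query$cell_meta$cluster))
  })
}

#' Specification for a synthetic bulk expression cohort
#'
#' Describes a gene-by-patient log2 expression table with binary imatinib
#' response labels in which the non-responder class has an elevated Pearson
#' correlation with a planted gene signature.
#'
#' @param n_positive Non-responders (the positive class for prediction).
#' @param n_negative Responders.
#' @param n_genes Genes in the cohort (must be >= the signature size).
#' @param signature_size Genes in the planted signature (used when no
#'   signature is supplied to \code{\link{generate_bulk_cohort}}).
#' @param effect_size_d Separation of the two classes' correlation scores in
#'   pooled-SD units (Cohen's d); 0 plants no effect.
#' @param noise_sd SD of the expression noise around each patient profile,
#'   log2 units.
#' @param score_sd Within-class SD of the planted per-patient correlation
#'   scores (the pooled SD that \code{effect_size_d} is expressed in).
#' @param base_cor Mean correlation of the responder class.
#' @param seed Integer seed.
#'
#' @return A \code{cohort_spec} list.
#' @export
cohort_spec <- function(n_positive = 20, n_negative = 20, n_genes = 500,
                        signature_size = 50, effect_size_d = 2,
                        noise_sd = 0.5, score_sd = 0.08, base_cor = 0.25,
                        seed = 1L) {
  spec <- list(n_positive = as.integer(n_positive),
               n_negative = as.integer(n_negative),
               n_genes = as.integer(n_genes),
               signature_size = as.integer(signature_size),
               effect_size_d = effect_size_d, noise_sd = noise_sd,
               score_sd = score_sd, base_cor = base_cor,
               seed = as.integer(seed))
  stopifnot(spec$n_positive >= 2, spec$n_negative >= 2,
            spec$signature_size >= 3,
            spec$signature_size <= spec$n_genes,
            spec$noise_sd > 0, spec$score_sd > 0)
  structure(spec, class = "cohort_spec")
}

#' Generate a synthetic bulk cohort with a planted signature correlation
#'
#' Each patient's profile over the signature genes is built as
#' \code{r * u + sqrt(1 - r^2) * w} on standardized centered vectors
#' (\code{u} the standardized signature, \code{w} orthogonal noise), so the
#' patient's Pearson correlation with the signature equals \code{r} exactly.
#' The per-patient \code{r} values are drawn from class-shifted normals with
#' common SD \code{score_sd}, with the non-responder mean elevated by
#' \code{effect_size_d * score_sd}. Because the correlation statistic is
#' planted exactly, the AUC of the downstream correlation classifier has the
#' closed form \code{pnorm(effect_size_d / sqrt(2))}. Remaining genes are
#' baseline plus N(0, noise_sd) noise, log2 scale.
#'
#' @param spec A \code{\link{cohort_spec}}.
#' @param signature Optional \code{\link{signature_profile}}; when NULL a
#'   signature of \code{spec$signature_size} genes is synthesized.
#'
#' @return List with \code{cohort} (a \code{\link{bulk_cohort}}),
#'   \code{signature} (the planted \code{signature_profile}) and \code{truth}
#'   (list: \code{r} planted correlation per patient, \code{labels}).
#' @export
generate_bulk_cohort <- function(spec, signature = NULL) {
  stopifnot(inherits(spec, "cohort_spec"))
  with_seed(spec$seed, {
    if (is.null(signature)) {
      signature <- signature_profile(
        genes = sprintf("SIG%03d", seq_len(spec$signature_size)),
        values = stats::rnorm(spec$signature_size, mean = 2, sd = 1),
        source_cluster = "planted")
    }
    m <- length(signature$gene)
    if (m > spec$n_genes)
      stop("signature has more genes than the cohort gene universe")
    if (stats::sd(signature$value) == 0)
      stop("signature values are constant; correlation is undefined")
    n_bg <- spec$n_genes - m
    genes <- c(signature$gene, if (n_bg) sprintf("BG%04d", seq_len(n_bg)))
    if (anyDuplicated(genes))
      stop("signature gene names collide with background gene names")
    n <- spec$n_positive + spec$n_negative
    labels <- factor(rep(c("nonresponder", "responder"),
                         c(spec$n_positive, spec$n_negative)),
                     levels = c("responder", "nonresponder"))
    shift <- ifelse(labels == "nonresponder",
                    spec$effect_size_d * spec$score_sd, 0)
    r <- stats::rnorm(n, mean = spec$base_cor + shift, sd = spec$score_sd)
    r <- pmin(pmax(r, -0.98), 0.98)

    u <- signature$value - mean(signature$value)
    u <- u / sqrt(sum(u^2))
    amp <- spec$noise_sd * sqrt(m)
    expr <- matrix(0, spec$n_genes, n,
                   dimnames = list(genes, sprintf("patient%03d", seq_len(n))))
    for (j in seq_len(n)) {
      e <- stats::rnorm(m)
      e <- e - mean(e)
      e <- e - sum(e * u) * u
      w <- e / sqrt(sum(e^2))
      expr[seq_len(m), j] <- 8 + amp * (r[j] * u + sqrt(1 - r[j]^2) * w)
    }
    if (n_bg) {
      baseline <- stats::rnorm(n_bg, 8, 1.5)
      expr[m + seq_len(n_bg), ] <- baseline +
        matrix(stats::rnorm(n_bg * n, 0, spec$noise_sd), n_bg, n)
    }
    cohort <- bulk_cohort(expr, labels)
    list(cohort = cohort, signature = signature,
         truth = list(r = stats::setNames(r, colnames(expr)),
                      labels = stats::setNames(labels, colnames(expr))))
  })
}
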