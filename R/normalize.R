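#' Normalization configuration
#'
#' Tuning constants for trimmed-mean-of-M-values (TMM) scaling factors and
#' log2 counts-per-million. Defaults follow the method's original definition:
#' 30% trim on each tail of the log-ratios (M), 5% on each tail of the
#' average log abundances (A), reference sample chosen as the one whose
#' 75th-percentile count fraction is closest to the mean across samples.
#'
#' @param m_trim Fraction trimmed from each tail of M (default 0.30).
#' @param a_trim Fraction trimmed from each tail of A (default 0.05).
#' @param pseudocount Added to counts before the log (default 0.5).
#' @param reference Either `"upper_quartile"` (automatic) or a sample
#'   identifier to use as the TMM reference.
#' @return List of class `norm_config`.
#' @export
norm_config <- function(m_trim = 0.30, a_trim = 0.05, pseudocount = 0.5,
                        reference = "upper_quartile") {
  if (m_trim < 0 || m_trim >= 0.5 || a_trim < 0 || a_trim >= 0.5)
    stopf("trim fractions must lie in [0, 0.5)")
  if (pseudocount <= 0) stopf("pseudocount must be positive")
  structure(list(m_trim = m_trim, a_trim = a_trim, pseudocount = pseudocount,
                 reference = reference),
            class = "norm_config")
}

#' Drop genes with zero counts in every sample
#'
#' All-zero genes carry no information and produce undefined M/A values in
#' TMM; they are removed before normalization and scoring.
#'
#' @param counts Gene-by-sample count matrix.
#' @return The matrix restricted to genes with a positive total.
#' @export
drop_zero_genes <- function(counts) {
  assert_count_matrix(counts)
  counts[rowSums(counts) > 0, , drop = FALSE]
}

tmm_reference_index <- function(counts, config) {
  if (!identical(config$reference, "upper_quartile")) {
    idx <- match(config$reference, colnames(counts))
    if (is.na(idx)) stopf("reference sample '%s' not found", config$reference)
    return(idx)
  }
  uq <- apply(counts, 2, function(x) quantile(x, 0.75)) / colSums(counts)
  which.min(abs(uq - mean(uq)))
}

# Doubly trimmed, inverse-variance weighted mean of M for one sample against
# the reference. Genes must have positive counts in both libraries.
tmm_one_factor <- function(obs, ref, n_obs, n_ref, m_trim, a_trim, sample_id) {
  keep <- obs > 0 & ref > 0
  if (!any(keep))
    stopf("sample '%s' shares no positively expressed genes with the TMM reference",
          sample_id)
  obs <- obs[keep]; ref <- ref[keep]
  p_o <- obs / n_obs; p_r <- ref / n_ref
  m <- log2(p_o / p_r)
  a <- 0.5 * log2(p_o * p_r)
  w <- 1 / ((n_obs - obs) / (n_obs * obs) + (n_ref - ref) / (n_ref * ref))

  n <- length(m)
  lo_m <- floor(n * m_trim) + 1; hi_m <- n + 1 - lo_m
  lo_a <- floor(n * a_trim) + 1; hi_a <- n + 1 - lo_a
  rm_ <- rank(m, ties.method = "first")
  ra_ <- rank(a, ties.method = "first")
  keep2 <- rm_ >= lo_m & rm_ <= hi_m & ra_ >= lo_a & ra_ <= hi_a
  if (!any(keep2)) return(1)
  2^(sum(w[keep2] * m[keep2]) / sum(w[keep2]))
}

#' TMM scaling factors
#'
#' For every sample against the reference, per-gene log-ratios
#' `M = log2((c_gj/N_j)/(c_gr/N_r))` and abundances
#' `A = (1/2) log2((c_gj/N_j) (c_gr/N_r))` are computed over genes positive
#' in both libraries; the most extreme `m_trim` fraction of M (each tail) and
#' `a_trim` fraction of A (each tail) are discarded; the factor is 2 to the
#' inverse-asymptotic-binomial-variance weighted mean of the surviving M.
#' Factors are rescaled so their geometric mean is 1.
#'
#' @param counts Gene-by-sample count matrix (all-zero genes removed).
#' @param config A [norm_config()].
#' @return Named numeric vector of per-sample factors, geometric mean 1.
#' @export
tmm_factors <- function(counts, config = norm_config()) {
  assert_count_matrix(counts)
  lib <- colSums(counts)
  if (any(lib <= 0)) stopf("every sample must have a positive library size")
  ref <- tmm_reference_index(counts, config)
  f <- vapply(seq_len(ncol(counts)), function(j)
    tmm_one_factor(counts[, j], counts[, ref], lib[j], lib[ref],
                   config$m_trim, config$a_trim, colnames(counts)[j]),
    numeric(1))
  f <- f / exp(mean(log(f)))
  names(f) <- colnames(counts)
  f
}

#' log2 counts-per-million on TMM effective library sizes
#'
#' Entry for gene g, sample j is
#' `log2((c_gj + p) / (N_j f_j) * 1e6)` with pseudocount `p` and effective
#' library size `N_j f_j`.
#'
#' @param counts Gene-by-sample count matrix.
#' @param factors Per-sample TMM factors (or all ones for plain CPM).
#' @param config A [norm_config()] (supplies the pseudocount).
#' @return Object of class `norm_matrix`: list with `logcpm` (real matrix),
#'   `factors`, `lib_sizes`, `pseudocount`.
#' @export
log2_cpm <- function(counts, factors = NULL, config = norm_config()) {
  assert_count_matrix(counts)
  lib <- colSums(counts)
  if (is.null(factors)) factors <- setNames(rep(1, ncol(counts)), colnames(counts))
  eff <- lib * factors[colnames(counts)]
  if (any(!is.finite(eff)) || any(eff <= 0))
    stopf("zero or undefined effective library size")
  logcpm <- log2(sweep(counts + config$pseudocount, 2, eff, "/") * 1e6)
  structure(list(logcpm = logcpm, factors = factors, lib_sizes = lib,
                 pseudocount = config$pseudocount),
            class = "norm_matrix")
}

#' Normalize a count matrix (TMM + log2-CPM)
#'
#' Convenience wrapper: drops all-zero genes, computes TMM factors, returns
#' the log2-CPM `norm_matrix`.
#'
#' @inheritParams tmm_factors
#' @export
normalize_counts <- function(counts, config = norm_config()) {
  counts <- drop_zero_genes(counts)
  f <- tmm_factors(counts, config)
  log2_cpm(counts, f, config)
}

#' @export
print.norm_matrix <- function(x, ...) {
  cat(sprintf("log2-CPM matrix: %d genes x %d samples (pseudocount %g)\n",
              nrow(x$logcpm), ncol(x$logcpm), x$pseudocount))
  cat(sprintf("TMM factors in [%.3f, %.3f], geometric mean %.6f\n",
              min(x$factors), max(x$factors), exp(mean(log(x$factors)))))
  invisible(x)
}

#' Pseudobulk aggregation of single-cell counts
#'
#' Sums counts within each sample x cluster cell group into one column named
#' `<sample>|<cluster>`. A cluster is flagged for exclusion from
#' cell-type-specific analyses when the number of samples holding fewer than
#' `min_cells` of its cells exceeds `max_deficient_samples`; flagged clusters
#' are reported, not silently dropped.
#'
#' @param sc A `single_cell_matrix` (see [simulate_single_cell()]), or any
#'   list with `counts` (cell x gene), `sample`, `cluster`.
#' @param min_cells Minimum cells per sample for a cluster to count as
#'   represented (default 10).
#' @param max_deficient_samples Number of deficient samples a cluster may
#'   have before exclusion (default 3; exclusion requires strictly more).
#' @param delim Column-name delimiter; occurrences inside labels are escaped.
#' @return List with `counts` (gene x sample|cluster matrix), `excluded`
#'   (cluster labels flagged for exclusion), `cell_counts` (sample x cluster
#'   table).
#' @export
pseudobulk <- function(sc, min_cells = 10L, max_deficient_samples = 3L,
                       delim = "|") {
  if (length(sc$sample) != nrow(sc$counts) || length(sc$cluster) != nrow(sc$counts))
    stopf("every cell needs exactly one sample and one cluster label")
  esc <- function(x) gsub(delim, paste0("\\", delim), x, fixed = TRUE)
  samples <- sort(unique(sc$sample))
  clusters <- sort(unique(sc$cluster))
  key <- paste(esc(sc$sample), esc(sc$cluster), sep = delim)
  groups <- split(seq_along(key), key)
  agg <- vapply(groups, function(idx)
    colSums(sc$counts[idx, , drop = FALSE]), numeric(ncol(sc$counts)))
  storage.mode(agg) <- "integer"

  tab <- table(factor(sc$sample, samples), factor(sc$cluster, clusters))
  deficient <- apply(tab < min_cells, 2, sum)
  excluded <- clusters[deficient > max_deficient_samples]

  list(counts = agg, excluded = excluded,
       cell_counts = as.matrix(tab))
}

#' Select the most variable genes
#'
#' Ranks genes by variance of log2-CPM across samples; ties broken by gene
#' identifier so the selection is deterministic.
#'
#' @param norm A `norm_matrix`.
#' @param n Number of genes (default 500).
#' @return Character vector of gene identifiers.
#' @export
select_variable_genes <- function(norm, n = 500L) {
  if (n <= 0) stopf("n must be positive")
  if (n > nrow(norm$logcpm)) stopf("n exceeds the number of genes")
  v <- apply(norm$logcpm, 1, var)
  ord <- order(-v, rownames(norm$logcpm))
  rownames(norm$logcpm)[ord][seq_len(n)]
}

#' PCA embedding of samples
#'
#' Per-gene centered singular value decomposition of the samples x genes
#' log2-CPM submatrix. Components are ordered by decreasing variance; the
#' sign convention makes each component's largest-magnitude gene loading
#' positive.
#'
#' @param norm A `norm_matrix`.
#' @param genes Genes to use (e.g. from [select_variable_genes()]).
#' @param n_components Number of components to return.
#' @return List with `embedding` (samples x components), `loadings`
#'   (genes x components), `explained_variance` (fractions of total).
#' @export
pca_embed <- function(norm, genes = rownames(norm$logcpm),
                      n_components = 2L) {
  x <- t(norm$logcpm[genes, , drop = FALSE])
  if (n_components > min(dim(x)))
    stopf("n_components exceeds matrix rank bound")
  if (all(apply(x, 2, var) < .Machine$double.eps))
    stopf("degenerate input: all genes constant across samples")
  pc <- prcomp(x, center = TRUE, scale. = FALSE)
  k <- seq_len(n_components)
  flip <- vapply(k, function(i) {
    l <- pc$rotation[, i]
    sign(l[which.max(abs(l))])
  }, numeric(1))
  list(embedding = sweep(pc$x[, k, drop = FALSE], 2, flip, "*"),
       loadings = sweep(pc$rotation[, k, drop = FALSE], 2, flip, "*"),
       explained_variance = (pc$sdev^2 / sum(pc$sdev^2))[k])
}
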