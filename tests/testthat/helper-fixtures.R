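# Shared fixture builders. Everything is generated in code at test time.

# Wrap a log2-CPM matrix as a norm_matrix without going through counts;
# used for arithmetic-level scoring/differential tests.
make_norm <- function(logcpm, factors = NULL, lib_sizes = NULL,
                      pseudocount = 0.5) {
  if (is.null(factors)) factors <- setNames(rep(1, ncol(logcpm)), colnames(logcpm))
  if (is.null(lib_sizes)) lib_sizes <- setNames(rep(1e6, ncol(logcpm)), colnames(logcpm))
  structure(list(logcpm = logcpm, factors = factors, lib_sizes = lib_sizes,
                 pseudocount = pseudocount),
            class = "norm_matrix")
}

# Random named count matrix
rand_counts <- function(n_genes, n_samples, seed, lambda = 50) {
  set.seed(seed)
  m <- matrix(rpois(n_genes * n_samples, lambda), n_genes, n_samples)
  rownames(m) <- sprintf("G%04d", seq_len(n_genes))
  colnames(m) <- sprintf("S%03d", seq_len(n_samples))
  storage.mode(m) <- "integer"
  m
}

# Small synthetic cohort used across modules: 3 cohorts of 20, LN effect 1
small_cohort <- function(seed = 1, effect = c(LN = 1, FMAC = 0, TEX = 0),
                         n_genes = 500, n_per = c(20L, 20L, 20L)) {
  simulate_cohort(sim_config(n_genes = n_genes, n_samples_per_cohort = n_per,
                             effect_log2fc = effect, seed = seed))
}

# Metadata row constructor for QC tests
qc_meta <- function(sample_id, ratio, bias, total,
                    cohort = "cohort1") {
  data.frame(sample_id = sample_id, cohort = cohort,
             timepoint = "leukapheresis", response = "responder",
             pfs_time = 1, pfs_event = 0L,
             intron_exon_ratio = ratio, five_three_bias = bias,
             total_counts = as.integer(total), stringsAsFactors = FALSE)
}

# Independent TMM oracle: direct transcription of the trimmed, weighted-mean
# definition (reference = sample whose 75th-percentile count fraction is
# closest to the mean; both-tail trims; inverse asymptotic binomial variance
# weights; geometric-mean rescaling).
tmm_oracle <- function(counts, m_trim = 0.3, a_trim = 0.05) {
  lib <- colSums(counts)
  uq <- apply(counts, 2, quantile, 0.75) / lib
  ref <- which.min(abs(uq - mean(uq)))
  f <- vapply(seq_len(ncol(counts)), function(j) {
    keep <- counts[, j] > 0 & counts[, ref] > 0
    o <- counts[keep, j]; r <- counts[keep, ref]
    M <- log2((o / lib[j]) / (r / lib[ref]))
    A <- 0.5 * log2((o / lib[j]) * (r / lib[ref]))
    w <- 1 / ((lib[j] - o) / (lib[j] * o) + (lib[ref] - r) / (lib[ref] * r))
    n <- length(M)
    loM <- floor(n * m_trim) + 1; hiM <- n + 1 - loM
    loA <- floor(n * a_trim) + 1; hiA <- n + 1 - loA
    rM <- rank(M, ties.method = "first"); rA <- rank(A, ties.method = "first")
    k <- rM >= loM & rM <= hiM & rA >= loA & rA <= hiA
    2^(sum(w[k] * M[k]) / sum(w[k]))
  }, numeric(1))
  f / exp(mean(log(f)))
}

# Independent module-score oracle: recomputes rank-based equal-frequency
# bins, the seeded control-draw protocol and the target/control means from
# scratch.
module_score_oracle <- function(logcpm, target_set, n_bins, controls_per_gene,
                                seed) {
  genes <- rownames(logcpm)
  means <- rowMeans(logcpm)
  ord <- order(means, genes)
  bin <- integer(length(genes))
  bin[match(genes[ord], genes)] <- ceiling(seq_along(genes) * n_bins / length(genes))
  names(bin) <- genes
  pools <- lapply(split(genes, bin), sort)
  targets <- target_set[target_set %in% genes]
  set.seed(seed)
  controls <- unlist(lapply(targets, function(g) {
    pool <- pools[[as.character(bin[[g]])]]
    sample(pool, controls_per_gene, replace = length(pool) < controls_per_gene)
  }))
  colMeans(logcpm[targets, , drop = FALSE]) -
    colMeans(logcpm[controls, , drop = FALSE])
}

# Independent Breslow partial log-likelihood (double loop over risk sets)
cox_pll_oracle <- function(beta, time, event, x) {
  s <- 0
  for (i in which(event == 1)) {
    risk <- time >= time[i]
    s <- s + beta * x[i] - log(sum(exp(beta * x[risk])))
  }
  s
}
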