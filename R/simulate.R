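#' Configuration for the synthetic cfRNA cohort generator
#'
#' Defines the generative model used for all simulation-based testing: gamma
#' baseline gene abundances, log-normal library sizes, negative-binomial
#' counts with a multiplicative responder effect on designated archetype
#' marker genes, exponential progression times with right censoring, and a
#' fraction of samples whose QC metric fields are overwritten to fail the
#' library filters.
#'
#' The default cohort sizes mirror the three study cohorts (28, 28, 35
#' samples). The default effect places a 1 log2-unit responder shift on the
#' LN-analog marker genes and none on FMAC/TEX, the configuration under which
#' the pipeline's signal-recovery behavior is studied.
#'
#' @param n_genes Number of genes.
#' @param n_samples_per_cohort Integer vector of per-cohort sample counts.
#' @param responder_fraction Probability a sample is a responder.
#' @param marker_gene_sets Named list of gene index vectors designated as
#'   archetype analogs; indices must be disjoint and `< n_genes`.
#' @param effect_log2fc Named numeric, one entry per marker set: log2
#'   multiplicative shift applied to that set's genes in responders.
#' @param nb_dispersion Negative-binomial dispersion `phi`
#'   (variance `mu + phi * mu^2`).
#' @param libsize_log_mean,libsize_log_sd Log-normal library-size parameters.
#' @param baseline_gene_mean_shape,baseline_gene_mean_rate Gamma parameters
#'   for per-gene relative abundance (normalized to sum to 1).
#' @param survival_baseline_hazard Baseline hazard per month.
#' @param survival_log_hr Log hazard ratio per unit covariate (default
#'   `-log(2)`: responders progress at half the baseline rate).
#' @param censor_time Administrative right-censoring time (months).
#' @param qc_fail_fraction Fraction of samples whose QC metrics are
#'   overwritten to violate a filter.
#' @param seed Integer seed; one global seed drives deterministic
#'   per-operation substreams.
#' @return List of class `sim_config`.
#' @export
sim_config <- function(n_genes = 2000L,
                       n_samples_per_cohort = c(28L, 28L, 35L),
                       responder_fraction = 0.5,
                       marker_gene_sets = NULL,
                       effect_log2fc = c(LN = 1, FMAC = 0, TEX = 0),
                       nb_dispersion = 0.05,
                       libsize_log_mean = log(5e6),
                       libsize_log_sd = 0.4,
                       baseline_gene_mean_shape = 0.6,
                       baseline_gene_mean_rate = 1,
                       survival_baseline_hazard = 0.04,
                       survival_log_hr = -log(2),
                       censor_time = 24,
                       qc_fail_fraction = 0,
                       seed = 1L) {
  if (is.null(marker_gene_sets)) {
    sets <- archetype_gene_sets()
    sizes <- lengths(sets)
    ends <- cumsum(sizes)
    marker_gene_sets <- Map(function(e, s) seq.int(e - s + 1L, e), ends, sizes)
    names(marker_gene_sets) <- names(sets)
  }
  cfg <- list(n_genes = as.integer(n_genes),
              n_samples_per_cohort = as.integer(n_samples_per_cohort),
              responder_fraction = responder_fraction,
              marker_gene_sets = marker_gene_sets,
              effect_log2fc = effect_log2fc,
              nb_dispersion = nb_dispersion,
              libsize_log_mean = libsize_log_mean,
              libsize_log_sd = libsize_log_sd,
              baseline_gene_mean_shape = baseline_gene_mean_shape,
              baseline_gene_mean_rate = baseline_gene_mean_rate,
              survival_baseline_hazard = survival_baseline_hazard,
              survival_log_hr = survival_log_hr,
              censor_time = censor_time,
              qc_fail_fraction = qc_fail_fraction,
              seed = as.integer(seed))
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  if (cfg$n_genes < 1 || any(cfg$n_samples_per_cohort < 1))
    stopf("dimensions must be positive")
  if (cfg$responder_fraction <= 0 || cfg$responder_fraction >= 1)
    stopf("responder_fraction must lie in (0, 1)")
  if (cfg$qc_fail_fraction < 0 || cfg$qc_fail_fraction >= 1)
    stopf("qc_fail_fraction must lie in [0, 1)")
  if (cfg$nb_dispersion <= 0) stopf("nb_dispersion must be positive")
  if (cfg$survival_baseline_hazard <= 0)
    stopf("survival_baseline_hazard must be positive")
  if (cfg$censor_time < 0) stopf("censor_time must be non-negative")
  idx <- unlist(cfg$marker_gene_sets, use.names = FALSE)
  if (anyDuplicated(idx)) stopf("marker gene sets must be disjoint")
  if (length(idx) && (min(idx) < 1 || max(idx) > cfg$n_genes))
    stopf("marker set index out of range (1..n_genes)")
  if (!all(names(cfg$marker_gene_sets) %in% names(cfg$effect_log2fc) |
           lengths(cfg$marker_gene_sets) == 0))
    stopf("every marker set needs an effect_log2fc entry")
  invisible(cfg)
}

# Gene identifiers: marker-set genes named with the packaged archetype
# symbols (so the shipped GMT applies to synthetic matrices), the rest
# synthetic.
sim_gene_ids <- function(cfg) {
  ids <- sprintf("GENE%05d", seq_len(cfg$n_genes))
  sets <- archetype_gene_sets()
  for (nm in names(cfg$marker_gene_sets)) {
    idx <- cfg$marker_gene_sets[[nm]]
    if (nm %in% names(sets) && length(idx) <= length(sets[[nm]]))
      ids[idx] <- sets[[nm]][seq_along(idx)]
    else
      ids[idx] <- sprintf("%s_MARKER%03d", nm, seq_along(idx))
  }
  ids
}

#' Simulate a multi-cohort cfRNA count matrix with metadata
#'
#' Counts for gene g in sample j are negative-binomial with mean
#' `lib_j * q_g * 2^(beta_g * r_j)`, where `r_j` indicates responder status
#' and `beta_g` is the configured log2 effect for marker-set genes (0
#' elsewhere). Metadata carries cohort, timepoint, response, a simulated
#' progression-free survival record whose hazard depends on response, and QC
#' metric fields; a configured fraction of samples has those metric fields
#' overwritten to violate one of the three library filters (counts are left
#' untouched — the filters operate on summary metrics only).
#'
#' @param config A [sim_config()] object.
#' @return List with `counts` (integer gene x sample matrix) and `metadata`
#'   (data.frame, one row per sample).
#' @export
simulate_cohort <- function(config) {
  validate_sim_config(config)
  n <- sum(config$n_samples_per_cohort)
  set.seed(derive_seed(config$seed, 1L))

  q <- rgamma(config$n_genes, shape = config$baseline_gene_mean_shape,
              rate = config$baseline_gene_mean_rate)
  q <- q / sum(q)
  lib <- rlnorm(n, config$libsize_log_mean, config$libsize_log_sd)
  responder <- rbinom(n, 1L, config$responder_fraction)

  beta <- numeric(config$n_genes)
  for (nm in names(config$marker_gene_sets))
    beta[config$marker_gene_sets[[nm]]] <- config$effect_log2fc[[nm]]

  mu <- (q %o% lib) * 2^(beta %o% responder)
  counts <- matrix(rnbinom(length(mu), mu = mu, size = 1 / config$nb_dispersion),
                   nrow = config$n_genes)
  rownames(counts) <- sim_gene_ids(config)
  colnames(counts) <- sprintf("S%03d", seq_len(n))
  storage.mode(counts) <- "integer"

  cohort <- rep(sprintf("cohort%d", seq_along(config$n_samples_per_cohort)),
                times = config$n_samples_per_cohort)
  timepoint <- sample(c("leukapheresis", "pre-lymphodepletion"), n, replace = TRUE)

  surv <- simulate_survival(responder, config,
                            seed = derive_seed(config$seed, 2L))

  # Nominal QC metrics for passing libraries
  intron_exon <- runif(n, 0.5, 2.5)
  bias <- stats::rnorm(n, 1, 0.05)
  total <- as.integer(pmin(colSums(counts), .Machine$integer.max))

  set.seed(derive_seed(config$seed, 3L))
  n_fail <- round_half_up(config$qc_fail_fraction * n)
  if (n_fail > 0) {
    fail_idx <- sample.int(n, n_fail)
    mode <- sample(c("dna_contamination", "rna_degradation", "low_depth"),
                   n_fail, replace = TRUE)
    intron_exon[fail_idx[mode == "dna_contamination"]] <-
      runif(sum(mode == "dna_contamination"), 3.5, 8)
    bias[fail_idx[mode == "rna_degradation"]] <-
      runif(sum(mode == "rna_degradation"), 2, 4)
    total[fail_idx[mode == "low_depth"]] <-
      as.integer(runif(sum(mode == "low_depth"), 1e3, 9e4))
  }

  metadata <- data.frame(
    sample_id = colnames(counts),
    cohort = cohort,
    timepoint = timepoint,
    response = ifelse(responder == 1L, "responder", "non-responder"),
    pfs_time = surv$time,
    pfs_event = surv$event,
    intron_exon_ratio = intron_exon,
    five_three_bias = bias,
    total_counts = total,
    stringsAsFactors = FALSE
  )
  list(counts = counts, metadata = metadata)
}

#' Simulate right-censored survival records
#'
#' Event times are exponential with hazard
#' `h0 * exp(log_hr * x)`; times beyond `censor_time` are right-censored
#' there.
#'
#' @param x Numeric covariate vector (binary group indicator or continuous
#'   score).
#' @param config A [sim_config()] (uses `survival_baseline_hazard`,
#'   `survival_log_hr`, `censor_time`).
#' @param seed Integer seed (defaults to a substream of `config$seed`).
#' @return data.frame with `time` and `event` (1 = observed, 0 = censored).
#' @export
simulate_survival <- function(x, config, seed = derive_seed(config$seed, 2L)) {
  if (!all(is.finite(x))) stopf("survival covariate must be finite")
  if (config$survival_baseline_hazard <= 0)
    stopf("survival_baseline_hazard must be positive")
  set.seed(seed)
  hazard <- config$survival_baseline_hazard * exp(config$survival_log_hr * x)
  t_event <- rexp(length(x), rate = hazard)
  data.frame(time = pmin(t_event, config$censor_time),
             event = as.integer(t_event <= config$censor_time))
}

#' Simulate labeled single-cell counts for pseudobulk testing
#'
#' Poisson counts per cell around cluster-specific expression profiles, with
#' every cell carrying exactly one sample label and one cluster label.
#'
#' @param n_samples,n_clusters Positive integers.
#' @param cells_per_cluster Either a scalar (same cell count for every
#'   sample x cluster cell group) or an `n_samples x n_clusters` integer
#'   matrix, allowing deliberately deficient clusters.
#' @param config A [sim_config()] (gene space and seed).
#' @param cell_depth Mean per-cell total count.
#' @return List of class `single_cell_matrix` with `counts` (cell x gene),
#'   `sample` and `cluster` label vectors.
#' @export
simulate_single_cell <- function(n_samples, n_clusters, cells_per_cluster,
                                 config, cell_depth = 2000) {
  if (n_samples < 1 || n_clusters < 1) stopf("dimensions must be positive")
  if (is.matrix(cells_per_cluster)) {
    if (!all(dim(cells_per_cluster) == c(n_samples, n_clusters)))
      stopf("cells_per_cluster matrix must be n_samples x n_clusters")
    ncell <- cells_per_cluster
  } else {
    ncell <- matrix(cells_per_cluster, n_samples, n_clusters)
  }
  set.seed(derive_seed(config$seed, 4L))
  q <- rgamma(config$n_genes, shape = config$baseline_gene_mean_shape,
              rate = config$baseline_gene_mean_rate)
  # cluster-specific profiles: baseline modulated per cluster
  profiles <- vapply(seq_len(n_clusters), function(k) {
    p <- q * rgamma(config$n_genes, shape = 5, rate = 5)
    p / sum(p)
  }, numeric(config$n_genes))

  sample_lab <- cluster_lab <- character(0)
  blocks <- list()
  for (s in seq_len(n_samples)) {
    for (k in seq_len(n_clusters)) {
      nc <- ncell[s, k]
      if (nc == 0) next
      lam <- profiles[, k] * cell_depth
      block <- matrix(rpois(nc * config$n_genes, rep(lam, each = nc)),
                      nrow = nc)
      blocks[[length(blocks) + 1L]] <- block
      sample_lab <- c(sample_lab, rep(sprintf("S%02d", s), nc))
      cluster_lab <- c(cluster_lab, rep(sprintf("C%02d", k), nc))
    }
  }
  counts <- do.call(rbind, blocks)
  colnames(counts) <- sim_gene_ids(config)
  rownames(counts) <- sprintf("cell%05d", seq_len(nrow(counts)))
  structure(list(counts = counts, sample = sample_lab, cluster = cluster_lab),
            class = "single_cell_matrix")
}
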