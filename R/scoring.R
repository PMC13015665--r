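#' Module scoring configuration
#'
#' Expression-level-controlled gene-set scoring: each target gene contributes
#' `controls_per_gene` background genes drawn from its expression bin, so the
#' control set matches the targets' expression-level distribution. Defaults
#' (25 bins, 100 controls per target gene) follow the scoring approach the
#' pipeline adopts.
#'
#' @param n_bins Number of equal-frequency expression bins (default 25).
#' @param controls_per_gene Control genes drawn per target gene (default 100).
#' @param seed Integer seed for the control draws.
#' @param rescale Rescale raw scores to the unit interval (default TRUE).
#' @return List of class `scoring_config`.
#' @export
scoring_config <- function(n_bins = 25L, controls_per_gene = 100L,
                           seed = 1L, rescale = TRUE) {
  if (n_bins < 1 || controls_per_gene < 1)
    stopf("n_bins and controls_per_gene must be positive")
  structure(list(n_bins = as.integer(n_bins),
                 controls_per_gene = as.integer(controls_per_gene),
                 seed = as.integer(seed), rescale = isTRUE(rescale)),
            class = "scoring_config")
}

#' Assign genes to equal-frequency expression bins
#'
#' Genes are ranked by mean log2-CPM across samples (ties broken by gene
#' identifier) and cut into `n_bins` equal-frequency bins.
#'
#' @param norm A `norm_matrix`.
#' @param n_bins Number of bins.
#' @return Named integer vector: bin index (1..n_bins) per gene.
#' @export
bin_genes_by_expression <- function(norm, n_bins = 25L) {
  genes <- rownames(norm$logcpm)
  if (length(genes) < n_bins) stopf("fewer genes than bins")
  means <- rowMeans(norm$logcpm)
  ord <- order(means, genes)
  rank_in <- match(genes, genes[ord])
  bins <- ceiling(rank_in * n_bins / length(genes))
  setNames(as.integer(bins), genes)
}

#' Draw expression-matched control genes for a target set
#'
#' For each target gene, `controls_per_gene` genes are drawn uniformly from
#' that gene's expression bin: without replacement when the bin holds at
#' least that many candidates, with replacement otherwise. Target genes are
#' themselves eligible as controls. Draws are reproducible under `seed`;
#' targets are processed in the order given, each bin's candidate list sorted
#' by identifier.
#'
#' @param target_set Character vector of target gene identifiers.
#' @param bins Bin assignment from [bin_genes_by_expression()].
#' @param controls_per_gene Controls drawn per target gene.
#' @param seed Integer seed.
#' @return List with `controls` (character multiset of control genes) and
#'   `missing` (target genes absent from the bin map, skipped with warning).
#' @export
sample_control_genes <- function(target_set, bins, controls_per_gene = 100L,
                                 seed = 1L) {
  present <- target_set[target_set %in% names(bins)]
  missing <- setdiff(target_set, present)
  if (length(missing))
    warnf("target gene(s) absent from matrix, skipped: %s",
          paste(missing, collapse = ", "))
  if (!length(present)) stopf("no target genes present in the expression matrix")
  by_bin <- split(names(bins), bins)
  by_bin <- lapply(by_bin, sort)
  set.seed(seed)
  controls <- unlist(lapply(present, function(g) {
    pool <- by_bin[[as.character(bins[[g]])]]
    if (length(pool) >= controls_per_gene)
      sample(pool, controls_per_gene, replace = FALSE)
    else
      sample(pool, controls_per_gene, replace = TRUE)
  }), use.names = FALSE)
  list(controls = controls, missing = missing, targets_used = present)
}

#' Raw module score
#'
#' Per sample: mean log2-CPM across the target genes minus the mean across
#' the control multiset.
#'
#' @param norm A `norm_matrix`.
#' @param target_set Target gene identifiers (those present are used).
#' @param controls Control multiset from [sample_control_genes()].
#' @return Named numeric vector of raw scores, one per sample.
#' @export
module_score <- function(norm, target_set, controls) {
  present <- intersect(target_set, rownames(norm$logcpm))
  if (!length(present)) stopf("empty effective target set")
  target_mean <- colMeans(norm$logcpm[present, , drop = FALSE])
  control_mean <- colMeans(norm$logcpm[controls, , drop = FALSE])
  target_mean - control_mean
}

#' Min-max rescaling to the unit interval
#'
#' `(x - min) / (max - min)`. A constant input is mapped to 0.5 everywhere
#' (with a warning): the min-max transform is undefined there and the
#' midpoint is the least-informative completion.
#'
#' @param x Numeric vector.
#' @return Vector in `[0, 1]`.
#' @export
rescale_unit <- function(x) {
  if (!all(is.finite(x))) stopf("non-finite values cannot be rescaled")
  rng <- range(x)
  if (rng[1] == rng[2]) {
    warnf("constant scores: min-max rescaling undefined, returning 0.5")
    return(setNames(rep(0.5, length(x)), names(x)))
  }
  (x - rng[1]) / (rng[2] - rng[1])
}

#' Score all archetype gene sets
#'
#' Bins genes once, then per gene set draws expression-matched controls
#' (substream seed derived from the set's position), computes raw scores and
#' min-max rescaled scores across the analyzed sample set.
#'
#' @param norm A `norm_matrix`.
#' @param gene_sets Named list of gene identifier vectors (e.g.
#'   [archetype_gene_sets()]).
#' @param config A [scoring_config()].
#' @return Object of class `module_score_table`: list with `scores`
#'   (data.frame: sample_id, `<set>_raw`, `<set>_scaled`), `manifest`
#'   (per-set control multiset, targets used, targets missing).
#' @export
score_archetypes <- function(norm, gene_sets, config = scoring_config()) {
  if (!length(gene_sets) || any(lengths(gene_sets) == 0))
    stopf("gene sets must be non-empty")
  bins <- bin_genes_by_expression(norm, config$n_bins)
  scores <- data.frame(sample_id = colnames(norm$logcpm),
                       stringsAsFactors = FALSE)
  manifest <- list()
  for (i in seq_along(gene_sets)) {
    nm <- names(gene_sets)[i]
    ctl <- sample_control_genes(gene_sets[[i]], bins, config$controls_per_gene,
                                seed = derive_seed(config$seed, i))
    raw <- module_score(norm, ctl$targets_used, ctl$controls)
    scores[[paste0(nm, "_raw")]] <- as.numeric(raw)
    if (config$rescale)
      scores[[paste0(nm, "_scaled")]] <- as.numeric(rescale_unit(raw))
    manifest[[nm]] <- ctl
  }
  structure(list(scores = scores, manifest = manifest, config = config),
            class = "module_score_table")
}

#' @export
print.module_score_table <- function(x, ...) {
  sets <- names(x$manifest)
  cat(sprintf("module scores: %d samples x %d gene sets (%s)\n",
              nrow(x$scores), length(sets), paste(sets, collapse = ", ")))
  invisible(x)
}
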