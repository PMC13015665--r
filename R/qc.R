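#' Sample quality thresholds
#'
#' Libraries are filtered on three criteria: DNA contamination (intron-to-exon
#' read ratio), RNA degradation (5'/3' coverage bias relative to the cohort
#' distribution), and sequencing depth (total feature-aligned reads). All
#' comparisons are strict, exactly as the rules are stated: ratio `> 3`
#' discards, bias `>` mean + 3 SD discards, depth `< 100000` discards.
#'
#' @param max_intron_exon_ratio Discard samples with intron/exon ratio
#'   strictly above this value (default 3).
#' @param bias_sd_multiplier Discard samples whose 5'/3' bias lies strictly
#'   more than this many standard deviations above the reference-group mean
#'   (default 3).
#' @param min_total_counts Discard samples with strictly fewer total
#'   feature-aligned reads than this (default 100000).
#' @return List of class `qc_thresholds`.
#' @export
qc_thresholds <- function(max_intron_exon_ratio = 3,
                          bias_sd_multiplier = 3,
                          min_total_counts = 100000L) {
  if (max_intron_exon_ratio <= 0 || bias_sd_multiplier <= 0 || min_total_counts <= 0)
    stopf("all QC thresholds must be positive")
  structure(list(max_intron_exon_ratio = max_intron_exon_ratio,
                 bias_sd_multiplier = bias_sd_multiplier,
                 min_total_counts = as.integer(min_total_counts)),
            class = "qc_thresholds")
}

#' Apply library-level sample quality filters
#'
#' Evaluates the three QC rules on the original (pre-filter) metric
#' distribution: the bias mean and SD are computed once on the full input set
#' (or per cohort) before any removal, never re-computed iteratively.
#'
#' @param meta Sample metadata (see [read_sample_metadata()]).
#' @param thresholds A [qc_thresholds()] object.
#' @param bias_reference One of `"all"` (bias mean/SD over the full analyzed
#'   set, the default) or `"cohort"` (computed within each sample's cohort).
#' @param frozen_bias_stats Optional `bias_stats` data.frame from a previous
#'   pass (columns `group`, `mean`, `sd`); when supplied, the degradation
#'   rule reuses those statistics instead of recomputing them, making the
#'   filter idempotent on an already-filtered set.
#' @return List with `kept` (sample ids), `discarded` (sample ids), `reasons`
#'   (named list of reason-code character vectors per discarded sample, codes
#'   among `dna_contamination`, `rna_degradation`, `low_depth`), and the
#'   frozen `bias_stats` used.
#' @export
apply_qc_filters <- function(meta, thresholds = qc_thresholds(),
                             bias_reference = c("all", "cohort"),
                             frozen_bias_stats = NULL) {
  bias_reference <- match.arg(bias_reference)
  validate_sample_metadata(meta)
  for (field in c("intron_exon_ratio", "five_three_bias", "total_counts")) {
    bad <- !is.finite(meta[[field]])
    if (any(bad))
      stopf("missing or non-finite QC metric '%s' for sample(s): %s",
            field, paste(meta$sample_id[bad], collapse = ", "))
  }

  if (!is.null(frozen_bias_stats)) {
    bias_stats <- frozen_bias_stats
    if (identical(bias_stats$group, "all")) {
      bias_cut <- rep(bias_stats$mean + thresholds$bias_sd_multiplier * bias_stats$sd,
                      nrow(meta))
    } else {
      idx <- match(as.character(meta$cohort), bias_stats$group)
      bias_cut <- bias_stats$mean[idx] + thresholds$bias_sd_multiplier * bias_stats$sd[idx]
    }
  } else if (bias_reference == "all") {
    mu <- mean(meta$five_three_bias)
    s <- sd(meta$five_three_bias)
    bias_cut <- rep(mu + thresholds$bias_sd_multiplier * s, nrow(meta))
    bias_stats <- data.frame(group = "all", mean = mu, sd = s)
  } else {
    mu <- tapply(meta$five_three_bias, meta$cohort, mean)
    s <- tapply(meta$five_three_bias, meta$cohort, sd)
    bias_cut <- (mu + thresholds$bias_sd_multiplier * s)[as.character(meta$cohort)]
    bias_stats <- data.frame(group = names(mu), mean = as.numeric(mu),
                             sd = as.numeric(s))
  }

  fails <- list(
    dna_contamination = meta$intron_exon_ratio > thresholds$max_intron_exon_ratio,
    rna_degradation   = meta$five_three_bias > bias_cut,
    low_depth         = meta$total_counts < thresholds$min_total_counts
  )
  any_fail <- Reduce(`|`, fails)
  reasons <- lapply(which(any_fail), function(i)
    names(fails)[vapply(fails, `[`, logical(1), i)])
  names(reasons) <- meta$sample_id[any_fail]

  list(kept = meta$sample_id[!any_fail],
       discarded = meta$sample_id[any_fail],
       reasons = reasons,
       bias_stats = bias_stats)
}
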