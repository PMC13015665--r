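#!/usr/bin/env Rscript
# Stage 4: progression-free survival stratified by LN module score.
#
# Splits retained samples at the median LN score (ties to "low"), estimates
# Kaplan-Meier curves per stratum, and tests the separation with the
# log-rank test and a univariate Cox model (Wald test) on the high/low
# indicator and on the continuous score.

suppressPackageStartupMessages(library(cfrnatme))

meta <- read_sample_metadata("results/data/metadata.tsv")
qc <- apply_qc_filters(meta, qc_thresholds())
kept_meta <- meta[match(qc$kept, meta$sample_id), ]
scores <- read.delim("results/module_scores.tsv")
stopifnot(identical(scores$sample_id, kept_meta$sample_id))

strata <- median_split(setNames(scores$LN_scaled, scores$sample_id))
km <- lapply(split(seq_along(strata), strata), function(idx)
  kaplan_meier(kept_meta$pfs_time[idx], kept_meta$pfs_event[idx]))
km_tab <- do.call(rbind, Map(cbind, stratum = names(km), km))
write.table(km_tab, "results/km_ln_stratified.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

lr <- logrank_test(kept_meta$pfs_time, kept_meta$pfs_event, strata)
cox_hl <- cox_univariate(as.integer(strata == "high"),
                         kept_meta$pfs_time, kept_meta$pfs_event)
cox_sc <- cox_univariate(scores$LN_scaled, kept_meta$pfs_time,
                         kept_meta$pfs_event)

cat(sprintf("log-rank chi-square = %.2f, p = %.3g\n", lr$statistic, lr$p_value))
cat(sprintf("Cox (high vs low LN): HR = %.2f, Wald z = %.2f, p = %.3g\n",
            cox_hl$effect_estimate, cox_hl$statistic, cox_hl$p_value))
cat(sprintf("Cox (continuous LN score): HR = %.2f per unit, p = %.3g\n",
            cox_sc$effect_estimate, cox_sc$p_value))
cat("HR < 1 means high-LN samples progress more slowly.\n")

jsonlite::write_json(
  list(logrank = list(chisq = lr$statistic, p = lr$p_value),
       cox_highlow = list(hr = cox_hl$effect_estimate, z = cox_hl$statistic,
                          p = cox_hl$p_value),
       cox_score = list(hr = cox_sc$effect_estimate, p = cox_sc$p_value)),
  "results/survival_tests.json", auto_unbox = TRUE, digits = NA)
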