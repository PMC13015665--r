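#!/usr/bin/env Rscript
# Stage 6: differential abundance and cross-cohort concordance.
#
# Uses cohorts 1 and 2 as the discovery set (per-gene Mann-Whitney tests on
# log2-CPM with BH control) and cohort 3 as the independent validation set;
# reports the Pearson correlation between discovery-significant log2 fold
# changes and the fold changes re-estimated in the validation cohort.

suppressPackageStartupMessages(library(cfrnatme))

counts <- read_count_matrix("results/data/counts.tsv")
meta <- read_sample_metadata("results/data/metadata.tsv")
qc <- apply_qc_filters(meta, qc_thresholds())
kept_meta <- meta[match(qc$kept, meta$sample_id), ]

disc_ids <- kept_meta$sample_id[kept_meta$cohort %in% c("cohort1", "cohort2")]
val_ids <- kept_meta$sample_id[kept_meta$cohort == "cohort3"]

norm_d <- normalize_counts(counts[, disc_ids])
norm_v <- normalize_counts(counts[, val_ids])
lab <- function(ids) kept_meta$response[match(ids, kept_meta$sample_id)]

tab <- differential_abundance(norm_d, lab(disc_ids))
tab <- tab[order(tab$adjusted_p), ]
write.table(tab, "results/differential_discovery.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

n_sig <- sum(tab$adjusted_p < 0.1)
cat(sprintf("discovery (cohorts 1+2, n = %d): %d transcripts at BH adj-p < 0.1\n",
            length(disc_ids), n_sig))
print(head(tab[, c("gene", "log2_fold_change", "adjusted_p")], 5))

val_fc <- log2_fold_change(norm_v, lab(val_ids))
conc <- cross_cohort_concordance(tab, val_fc, adj_p_threshold = 0.1)
cat(sprintf("validation (cohort 3, n = %d): Pearson r = %.2f over %d significant transcripts\n",
            length(val_ids), conc$r, conc$n_genes))

jsonlite::write_json(list(n_significant = n_sig, pearson_r = conc$r,
                          n_genes_compared = conc$n_genes),
                     "results/concordance.json", auto_unbox = TRUE, digits = NA)
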