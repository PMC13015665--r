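#!/usr/bin/env Rscript
# Stage 2: library QC and normalization.
#
# Applies the three library filters (intron/exon ratio > 3; 5'/3' bias above
# cohort mean + 3 SD; < 100,000 feature-aligned reads), then computes TMM
# scaling factors and log2-CPM on the retained samples. Also records the
# top-500 variable-gene PCA coordinates used to check for cohort/timepoint
# batch structure.

suppressPackageStartupMessages(library(cfrnatme))

counts <- read_count_matrix("results/data/counts.tsv")
meta <- read_sample_metadata("results/data/metadata.tsv")

qc <- apply_qc_filters(meta, qc_thresholds())
cat(sprintf("QC: retained %d of %d samples\n", length(qc$kept), nrow(meta)))
reason_tab <- table(unlist(qc$reasons))
if (length(reason_tab)) print(reason_tab)

qc_report <- data.frame(
  sample_id = meta$sample_id,
  status = ifelse(meta$sample_id %in% qc$kept, "pass",
                  vapply(meta$sample_id, function(s)
                    paste(qc$reasons[[s]], collapse = ";"), "")))
write.table(qc_report, "results/qc_report.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

norm <- normalize_counts(counts[, qc$kept])
cat(sprintf("TMM factors span [%.3f, %.3f]\n",
            min(norm$factors), max(norm$factors)))

write.table(data.frame(sample_id = names(norm$factors),
                       tmm_factor = norm$factors,
                       lib_size = norm$lib_sizes),
            "results/tmm_factors.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
write.table(data.frame(gene_id = rownames(norm$logcpm), norm$logcpm,
                       check.names = FALSE),
            "results/log2cpm.tsv", sep = "\t", quote = FALSE, row.names = FALSE)

vg <- select_variable_genes(norm, 500)
pca <- pca_embed(norm, vg, n_components = 2)
kept_meta <- meta[match(qc$kept, meta$sample_id), ]
write.table(data.frame(sample_id = rownames(pca$embedding),
                       PC1 = pca$embedding[, 1], PC2 = pca$embedding[, 2],
                       cohort = kept_meta$cohort,
                       timepoint = kept_meta$timepoint),
            "results/pca_top500.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
cat(sprintf("PCA on top 500 variable genes: PC1 %.1f%%, PC2 %.1f%% of variance\n",
            100 * pca$explained_variance[1], 100 * pca$explained_variance[2]))
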