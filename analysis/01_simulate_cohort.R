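#!/usr/bin/env Rscript
# Stage 1: generate the synthetic study cohort.
#
# Emulates the structure of the cfRNA study data: three cohorts (28/28/35
# samples), negative-binomial counts over 2,000 genes, a 1 log2-unit
# responder shift on the 20 LN archetype marker analogs, exponential
# progression times with responders at half the baseline hazard, and 10% of
# samples with QC-failing library metrics. Writes the count matrix and
# metadata used by every later stage.

suppressPackageStartupMessages(library(cfrnatme))

seed <- 1L
outdir <- "results/data"
dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

cfg <- sim_config(qc_fail_fraction = 0.1, seed = seed)
sim <- simulate_cohort(cfg)

write_count_matrix(sim$counts, file.path(outdir, "counts.tsv"))
write_sample_metadata(sim$metadata, file.path(outdir, "metadata.tsv"))

cat(sprintf("simulated %d genes x %d samples across %d cohorts\n",
            nrow(sim$counts), ncol(sim$counts),
            length(unique(sim$metadata$cohort))))
print(table(sim$metadata$cohort, sim$metadata$response))
cat(sprintf("median library size: %.2fM feature counts\n",
            median(colSums(sim$counts)) / 1e6))
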