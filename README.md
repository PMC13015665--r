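# cfrnatme

Analysis pipeline for pre-treatment plasma **cell-free RNA (cfRNA)**
profiling of CAR T-cell therapy response in large B-cell lymphoma. Plasma
cfRNA is shed by both circulating and tissue-resident cells, so it can carry
transcriptional signatures of the **tumor microenvironment (TME)** —
normally accessible only through invasive biopsies — in a standard blood
draw. This package implements, as tested and reusable functions, every
computational stage needed to ask whether TME *archetype* signatures (lymph
node-like **LN**, follicular macrophage and accessory cell **FMAC**, T-cell
exhausted **TEX**, each a 20-gene marker set) measured in pre-treatment
plasma predict durable response and progression-free survival (PFS):

1. **Library QC** — samples discarded when intron/exon read ratio > 3
   (DNA contamination), 5′/3′ coverage bias > cohort mean + 3 SD (RNA
   degradation), or < 100,000 feature-aligned reads.
2. **Normalization** — TMM scaling factors (trimmed mean of M-values:
   double-trimmed, inverse-variance-weighted mean of per-gene log-ratios
   against an upper-quartile reference) and log2 counts-per-million,
   `log2((c + 0.5) / (N·f) · 10⁶)`.
3. **Module scoring** — the central statistic. For gene set *G* and sample
   *j*: `score_j = mean_{g∈G} x_gj − mean_{c∈C} x_cj`, where the control
   multiset *C* draws 100 genes per target gene from the target's
   expression bin (25 equal-frequency bins on mean log2-CPM), then min-max
   rescaling to [0, 1]. The expression-matched background removes the
   abundance component that dominates naive set means.
4. **Survival stratification** — median split of the LN score (ties low),
   Kaplan–Meier curves, log-rank test, univariate Cox partial-likelihood
   fit (Newton–Raphson, Breslow ties) with Wald test.
5. **Predictive modeling** — Monte Carlo cross-validation: 101 iterations
   of response-stratified 70/30 splits, L1-penalized logistic regression
   with 5-fold inner CV for the penalty, held-out AUC, and
   feature-recurrence analysis (fraction of iterations selecting each
   transcript).
6. **Differential abundance** — per-gene Mann–Whitney tests on log2-CPM
   with Benjamini–Hochberg control in discovery cohorts, and Pearson
   concordance of significant log2 fold changes with an independent
   validation cohort.

A negative-binomial **synthetic cohort generator** (`sim_config()`,
`simulate_cohort()`, `simulate_survival()`, `simulate_single_cell()`)
emulates the study's data structure — three cohorts of 28/28/35 samples,
log-normal library sizes, a configurable multiplicative responder effect on
archetype marker genes, right-censored exponential PFS, labeled single-cell
fixtures for pseudobulk aggregation — so the entire pipeline is testable
without any download.

## Worked example

The `analysis/` directory holds the numbered workflow; each stage is a thin
driver over package functions and writes its tables under `results/`:

```sh
Rscript analysis/01_simulate_cohort.R
Rscript analysis/02_qc_normalize.R
Rscript analysis/03_module_scores.R
Rscript analysis/04_survival.R
Rscript analysis/05_predictive_cv.R
Rscript analysis/06_differential.R
```

Output of stages 3 and 4 on the default synthetic cohort (seed 1):

```
LN   median score responders 0.875 vs non-responders 0.135, MW p = 6.82e-15
FMAC median score responders 0.475 vs non-responders 0.485, MW p = 0.444
TEX  median score responders 0.528 vs non-responders 0.571, MW p = 0.945

log-rank chi-square = 6.56, p = 0.0104
Cox (high vs low LN): HR = 0.42, Wald z = -2.49, p = 0.013
```

Read: the injected LN marker effect separates responders decisively while
FMAC/TEX (no injected effect) stay at chance, and samples with
above-median LN scores progress at less than half the hazard of the rest.
Stage 6 reports that fold changes of discovery-significant transcripts
(cohorts 1+2) are strongly correlated with those re-estimated in cohort 3
(`Pearson r = 0.73 over 21 significant transcripts`), mirroring the
cross-cohort reproducibility analysis.

Equivalent programmatic entry point:

```r
library(cfrnatme)
sim <- simulate_cohort(sim_config(qc_fail_fraction = 0.1, seed = 1))
manifest <- run_full_pipeline(pipeline_config(
  counts = sim$counts, metadata = sim$metadata, seed = 1))
generate_report(manifest)$auc_summary
```

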