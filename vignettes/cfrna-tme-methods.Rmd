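---
title: "Methods: TME archetype signatures in plasma cfRNA"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: TME archetype signatures in plasma cfRNA}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cfrnatme)
```

## The problem and the pipeline's shape

Response to anti-CD19 CAR T-cell therapy in large B-cell lymphoma varies
widely, and the state of the tumor microenvironment (TME) before treatment
is a known determinant. TME transcriptional *archetypes* — lymph node-like
(LN), follicular macrophage and accessory cell (FMAC) and T-cell exhausted
(TEX), each summarized by a 20-gene marker list — have been defined from
tumor biopsies, but biopsies are invasive and not routinely collected.
Plasma cell-free RNA (cfRNA) aggregates transcripts shed by circulating
*and* tissue-resident cells, so archetype activity may be measurable from a
blood draw.

The package implements the full analysis as composable stages: library QC →
TMM/log2-CPM normalization → expression-controlled module scoring →
survival stratification → Monte Carlo cross-validated sparse classification
→ differential abundance with cross-cohort concordance. Every stage is
exercised end-to-end on a synthetic cohort generator, which is first-class,
tested code, not a fixture.

## Sample quality filters

Three library-level rules, all strict inequalities exactly as specified:
intron-to-exon read ratio > 3 discards (cfDNA contamination inflates
intronic signal); 5′/3′ coverage bias strictly above the reference-group
mean + 3 SD discards (RNA degradation); total feature-aligned reads
< 100,000 discards. The bias reference statistics are computed **once** on
the pre-filter sample set — no iterative re-computation — and the reference
group defaults to the full analyzed set rather than per cohort: at roughly
30 samples per cohort a pooled mean/SD is substantially stabler, and the
per-cohort option remains available (`bias_reference = "cohort"`). A
consequence of the relative rule worth knowing: in a cohort of $n$ samples
the largest attainable z-score is $(n-1)/\sqrt{n}$, so no single outlier
can exceed 3 SD for $n \le 10$, and co-occurring outliers inflate the SD
and can mask one another. The filters operate on summary metrics only,
never on the counts.

## Normalization

TMM scaling factors follow the method's original definition, which the
source analysis names without constants: per sample versus a reference
(the sample whose 75th-percentile count fraction is closest to the mean),
per-gene log-ratios $M$ and average log-abundances $A$ are computed over
genes positive in both libraries; 30% of each tail of $M$ and 5% of each
tail of $A$ are discarded; the factor is $2^{\bar M_w}$ with weights equal
to the inverse asymptotic binomial variance; factors are rescaled to
geometric mean 1. Abundance is quantified as
$\log_2\!\big((c_{gj} + 0.5)\,/\,(N_j f_j) \cdot 10^6\big)$. The 0.5
pseudocount with effective library $N_j f_j$ is one of several log-CPM
dialects; it was chosen for exact testability (the zero-count level is
known in closed form per sample) and is exposed in `norm_config()`. Genes
with zero counts in every sample are dropped before TMM and scoring: they
carry no information and produce undefined $M/A$ values.

Single-cell data enter only as pseudobulk: counts summed within each
sample × cluster group, with a cluster flagged for exclusion from
cell-type-specific analyses when it has fewer than 10 cells in more than 3
samples (both bounds strict, applied over all samples in the object).
Cluster labels are inputs; no clustering is performed here.

## Module scoring

For a gene set $G$ the raw score of sample $j$ is the mean log2-CPM over
$G$ minus the mean over an expression-matched control multiset: 100 control
genes per target gene, drawn from the target's bin among 25
equal-frequency expression bins on mean log2-CPM. Design choices where the
source description leaves latitude:

- **Equal-frequency (rank-based) bins**, ties broken by gene identifier —
  matches the scoring approach this method adapts and cannot produce empty
  bins.
- **Draws without replacement** when a bin holds at least 100 candidates,
  with replacement otherwise; seed-controlled, targets processed in listed
  order over identifier-sorted pools, so a from-scratch reimplementation of
  the protocol reproduces the multiset bit-for-bit.
- **Target genes stay eligible as controls** (the adapted approach does not
  exclude them); exclusion is a sensitivity knob one could add, not the
  default.
- **One control manifest per set**, shared across samples.
- **Absent target genes are dropped with a warning** and recorded in the
  manifest — cfRNA matrices routinely miss genes — rather than failing.
- **Min-max rescaling to [0, 1]** is computed over the analyzed sample set
  jointly (cohorts are plotted together in the source analysis); constant
  input maps to 0.5 with a warning, the least-informative completion of a
  transform that is otherwise undefined.

The raw score is invariant to adding any per-sample constant (target and
control means shift equally), which is exactly why the matched background
is used: it cancels expression-level composition effects that a naive set
mean would absorb.

## Survival analysis

Samples are stratified at the median score, ties assigned to "low" to
match the asymmetric wording "above median (high) and below-median (low)".
Kaplan–Meier estimation and the log-rank test wrap the survival package;
the univariate Cox model is fit in-package by Newton–Raphson on the
partial likelihood with **Breslow** tie handling (chosen over Efron for
exact oracle testability; the returned object records the convention),
converging when the absolute score falls below 1e-8 (at most 50
iterations, steps damped at 5). Monotone likelihoods — event order
following the covariate ranking — are detected by divergence of the
coefficient and reported as a flagged error rather than a finite estimate.
The headline Wald test is interpreted as univariate Cox on the high/low
indicator; the continuous-score Cox is computed alongside since the source
does not state which parameterization produced its p-value, and neither is
asserted as "the" original model.

## Monte Carlo cross-validation

Each of 101 iterations draws a response-stratified split: per class,
round-half-up of 70% to training. Features are standardized with
**train-fold statistics only**; the L1 penalty $\lambda$ (multiplying
$\|\beta\|_1$ added to the per-sample mean negative log-likelihood) is
selected by stratified 5-fold inner CV maximizing held-out AUC — the same
metric as the outer loop — with ties broken toward the larger, sparser
$\lambda$. The grid is 30 log-spaced values over $[10^{-3}, 10^2]$; grid,
scale and objective are config-exposed because the source names only the
solver family. The solver behind `fit_lasso_logistic()` is glmnet's
coordinate descent (the source analysis likewise used an off-the-shelf
solver); KKT conditions at the returned solution are asserted in the test
suite. AUC is computed as the normalized Mann–Whitney U (ties half), and
per-iteration RNG derives from `(seed, iteration)`, so serial and parallel
execution agree. The "all transcripts" feature set is restricted to genes
detected (non-zero count) in at least 25% of *training* samples, computed
per iteration without touching the test partition.

## Differential abundance and concordance

The per-gene machinery is a deliberate stand-in, not a reimplementation of
negative-binomial GLM frameworks: log2 fold change is the difference of
group means of log2-CPM (exactly testable; it diverges from shrunken
count-model estimators, and is documented as such), the per-gene test is
the pipeline's default two-sided Mann–Whitney U, and BH adjustment wraps
`p.adjust`. The discovery/validation design is preserved exactly: cohorts
1+2 discover at BH adj-p < 0.1, cohort 3 re-estimates fold changes, and
Pearson correlation over the discovery-significant genes measures
concordance. The significance threshold is a parameter because the source
does not fully specify whether its correlation used all significant
transcripts or a further-filtered subset.

## The synthetic cohort generator

Counts are negative-binomial with mean
$\mathrm{lib}_j \cdot q_g \cdot 2^{\beta_g r_j}$ and variance
$\mu + \phi\mu^2$ — the standard RNA-seq count model, fixed here because
the source describes no generative model. $q_g$ is gamma(shape 0.6)
relative abundance (normalized to sum 1; the sub-1 shape yields the
realistic long tail of low-abundance genes), $\mathrm{lib}_j$ log-normal
around 5 million feature counts (matching the reported unique-feature
depth), $r_j$ the responder indicator, and $\beta_g$ the configured log2
effect on marker-set genes. Defaults mirror the study structure: cohorts
of 28/28/35, responder fraction 0.5 (per-cohort fractions are not
reported, so this is configurable, not asserted), a 1 log2-unit LN-marker
effect and none on FMAC/TEX. Marker-set genes are named with the packaged
archetype symbols so the shipped GMT applies directly to synthetic
matrices. PFS times are exponential with hazard
$h_0 e^{\beta x}$ ($h_0 = 0.04$/month, responders at half hazard,
censoring at 24 months); the covariate may be a binary group or a
continuous score, since the analysis stratifies by median but tests with a
Wald statistic. QC failures are injected by overwriting metric fields only
— never counts — because the filters operate on metrics. One integer seed
drives deterministic per-operation substreams.

The default dispersion $\phi = 0.05$ was fixed analytically from the
generator's own null-calibration contract: the group-mean difference of
per-gene log2 expression at 200 samples/group has SD
$\approx \sqrt{2(\phi + 1/\mu)/(n\ln^2 2)}$, and $\phi = 0.05$ keeps 95% of
null genes within ±0.1, which the test suite verifies. Real patient
cohorts are more dispersed (biological $\phi$ of 0.2–1 is common in cfRNA);
the knob is configurable, and passing signal-recovery tests at $\phi = 0.05$
demonstrates correctness of the machinery, **not** that comparable AUCs are
attainable on clinical data. More generally the generator emulates the
*statistical structure* the pipeline assumes — library-size variation,
abundance skew, multiplicative group effects, censored survival — and not
cfRNA-specific features such as fragment-length biology, tissue-of-origin
mixtures, batch structure, or correlated co-expression modules; null
calibration and parameter recovery on it are necessary, not sufficient,
evidence about real data.

## Problem sizes and numerical tolerances

The shipped tests run the scorer against an independent brute-force oracle
at 200 genes × 12 samples (agreement to 1e-12), TMM against a from-scratch
implementation at 50 × 4 (1e-10), signal recovery at 100 simulation
replicates of 60 samples, cross-validated recovery at 101 iterations (20
replicate runs for the recurrence analysis, 11 permutation replicates for
the null band), survival recovery at n = 500, and concordance at 2,000
genes with 30 samples per cohort — sizes chosen to exercise every code
path at desk scale. Cox convergence uses |score| < 1e-8; the lasso solver
runs at threshold 1e-12 with a short warm-started path down to the target
$\lambda$; BH, rescaling and AUC are exact closed forms.

## Known limitations

- The differential module's mean-difference fold change and rank test will
  not reproduce shrunken NB-GLM estimates on real data; it preserves the
  design, not the estimator.
- The Cox implementation is univariate by design; clinical covariate
  adjustment is out of scope.
- Pseudobulk assumes cluster labels are given; no clustering or embedding
  is provided.
- The FMAC marker list ships the token "CLEC14 CD36" verbatim as printed
  in its source; whether it denotes one gene or two (CLEC14A, CD36) cannot
  be resolved from the text, so FMAC carries 19 members.
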