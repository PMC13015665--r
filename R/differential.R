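#' Per-gene log2 fold change between response groups
#'
#' Difference of group means of log2-CPM (responder minus non-responder).
#' This is a deliberately simple, exactly testable estimator; it is a
#' stand-in for shrunken count-model estimators, not a reimplementation of
#' them.
#'
#' @param norm A `norm_matrix`.
#' @param labels Binary response labels, one per sample; the positive group
#'   is `"responder"` when present, else the second factor level.
#' @return Named numeric vector of per-gene log2 fold changes.
#' @export
log2_fold_change <- function(norm, labels) {
  grp <- response_indicator(labels)
  if (sum(grp == 1) == 0 || sum(grp == 0) == 0)
    stopf("both response groups must be non-empty")
  rowMeans(norm$logcpm[, grp == 1, drop = FALSE]) -
    rowMeans(norm$logcpm[, grp == 0, drop = FALSE])
}

response_indicator <- function(labels) {
  if (is.character(labels) || is.factor(labels)) {
    lab <- as.character(labels)
    if ("responder" %in% lab) return(as.integer(lab == "responder"))
  }
  as.integer(as.factor(labels)) - 1L
}

#' Per-gene two-group test
#'
#' Two-sided Mann-Whitney U on log2-CPM per gene (the pipeline's default
#' comparison). Genes with all values tied across both groups get p = 1 and
#' a degenerate flag.
#'
#' @inheritParams log2_fold_change
#' @return data.frame with `gene`, `p_value`, `degenerate`.
#' @export
per_gene_test <- function(norm, labels) {
  grp <- response_indicator(labels)
  if (sum(grp == 1) < 3 || sum(grp == 0) < 3)
    stopf("need at least 3 samples per group")
  x1 <- norm$logcpm[, grp == 1, drop = FALSE]
  x0 <- norm$logcpm[, grp == 0, drop = FALSE]
  res <- vapply(seq_len(nrow(norm$logcpm)), function(g) {
    a <- x1[g, ]; b <- x0[g, ]
    if (length(unique(c(a, b))) == 1) return(c(1, 1))
    c(mann_whitney_u(a, b)$p_value, 0)
  }, numeric(2))
  data.frame(gene = rownames(norm$logcpm), p_value = res[1, ],
             degenerate = res[2, ] == 1, row.names = NULL)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR adjustment (`p * m / rank` with monotonicity enforcement,
#' capped at 1).
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values, order-preserving.
#' @export
bh_adjust <- function(p) {
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1))
    stopf("p-values must lie in [0, 1]")
  p.adjust(p, method = "BH")
}

#' Differential abundance table
#'
#' Combines [log2_fold_change()], [per_gene_test()] and [bh_adjust()] into
#' one per-gene result table.
#'
#' @inheritParams log2_fold_change
#' @return data.frame with `gene`, `log2_fold_change`, `p_value`,
#'   `adjusted_p`, `degenerate`.
#' @export
differential_abundance <- function(norm, labels) {
  fc <- log2_fold_change(norm, labels)
  tst <- per_gene_test(norm, labels)
  data.frame(gene = tst$gene,
             log2_fold_change = as.numeric(fc[tst$gene]),
             p_value = tst$p_value,
             adjusted_p = bh_adjust(tst$p_value),
             degenerate = tst$degenerate,
             row.names = NULL)
}

#' Pearson product-moment correlation
#'
#' @param x,y Equal-length numeric vectors (length >= 3, both non-constant).
#' @return Correlation in `[-1, 1]`.
#' @export
pearson_correlation <- function(x, y) {
  if (length(x) != length(y)) stopf("vectors must have equal length")
  if (length(x) < 3) stopf("need at least 3 points")
  if (var(x) == 0 || var(y) == 0) stopf("constant vector: correlation undefined")
  cor(x, y, method = "pearson")
}

#' Cross-cohort fold-change concordance
#'
#' Restricts the discovery table to genes significant at the BH-adjusted
#' threshold, inner-joins with the validation fold changes on gene
#' identifier, and reports their Pearson correlation.
#'
#' @param discovery Differential table from [differential_abundance()] on the
#'   discovery cohorts.
#' @param validation_fc Named per-gene log2 fold-change vector from the
#'   validation cohort.
#' @param adj_p_threshold Discovery significance cut (default 0.1).
#' @return List with `r` (Pearson correlation), `n_genes` (genes compared),
#'   `genes`.
#' @export
cross_cohort_concordance <- function(discovery, validation_fc,
                                     adj_p_threshold = 0.1) {
  sig <- discovery[discovery$adjusted_p < adj_p_threshold, , drop = FALSE]
  common <- intersect(sig$gene, names(validation_fc))
  if (length(common) < 3)
    stopf("fewer than 3 overlapping significant genes: concordance undefined")
  d_fc <- sig$log2_fold_change[match(common, sig$gene)]
  v_fc <- as.numeric(validation_fc[common])
  list(r = pearson_correlation(d_fc, v_fc), n_genes = length(common),
       genes = common)
}
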