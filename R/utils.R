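#' @keywords internal
"_PACKAGE"

#' @importFrom stats median prcomp pchisq pnorm quantile rbinom rexp rgamma
#'   rlnorm rnbinom rpois runif sd var wilcox.test cor p.adjust qnorm IQR
#'   plogis setNames
#' @importFrom utils read.delim write.table head
NULL

# Derive a per-operation substream seed from a global seed. Kept below 2^31-1
# so the result is always a valid R integer seed.
derive_seed <- function(seed, index) {
  as.integer((as.numeric(seed) * 7919 + as.numeric(index) * 104729) %% 2147483647)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

assert_count_matrix <- function(counts) {
  if (!is.matrix(counts)) stopf("counts must be a matrix")
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stopf("count matrix must carry gene row names and sample column names")
  if (anyDuplicated(rownames(counts)))
    stopf("duplicate gene identifiers in count matrix")
  if (anyDuplicated(colnames(counts)))
    stopf("duplicate sample identifiers in count matrix")
  if (any(counts < 0)) stopf("counts must be non-negative")
  invisible(counts)
}

# Round-half-up (base round() is round-half-even)
round_half_up <- function(x) floor(x + 0.5)
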