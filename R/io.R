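#' Read a gene-by-sample count matrix
#'
#' Reads raw counts either from a tab-separated table whose first column holds
#' gene identifiers, or from a MatrixMarket coordinate file accompanied by
#' `genes.txt` / `samples.txt` sidecar files in the same directory.
#'
#' @param path Path to the counts TSV or `.mtx` file.
#' @param format `"tsv"` or `"mtx"`.
#' @return Integer matrix (genes x samples) with unique dimnames.
#' @export
read_count_matrix <- function(path, format = c("tsv", "mtx")) {
  format <- match.arg(format)
  if (!file.exists(path)) stopf("count file not found: %s", path)
  if (format == "tsv") {
    tab <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
    if (ncol(tab) < 2) stopf("count TSV %s has no sample columns", path)
    genes <- as.character(tab[[1]])
    if (anyDuplicated(genes)) {
      dup <- unique(genes[duplicated(genes)])
      stopf("duplicate gene identifiers in %s: %s", path,
            paste(head(dup, 5), collapse = ", "))
    }
    counts <- as.matrix(tab[, -1, drop = FALSE])
    if (!is.numeric(counts)) stopf("non-numeric counts in %s", path)
    rownames(counts) <- genes
  } else {
    m <- Matrix::readMM(path)
    side <- function(f) {
      p <- file.path(dirname(path), f)
      if (!file.exists(p)) stopf("missing sidecar file %s for %s", f, path)
      readLines(p)
    }
    counts <- as.matrix(m)
    rownames(counts) <- side("genes.txt")
    colnames(counts) <- side("samples.txt")
  }
  storage.mode(counts) <- "integer"
  assert_count_matrix(counts)
  counts
}

#' Write a count matrix
#'
#' @param counts Integer gene-by-sample matrix.
#' @param path Output path (TSV; or `.mtx` with sidecars for `format = "mtx"`).
#' @param format `"tsv"` or `"mtx"`.
#' @export
write_count_matrix <- function(counts, path, format = c("tsv", "mtx")) {
  format <- match.arg(format)
  assert_count_matrix(counts)
  if (format == "tsv") {
    tab <- data.frame(gene_id = rownames(counts), counts, check.names = FALSE)
    write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    Matrix::writeMM(Matrix::Matrix(counts, sparse = TRUE), path)
    writeLines(rownames(counts), file.path(dirname(path), "genes.txt"))
    writeLines(colnames(counts), file.path(dirname(path), "samples.txt"))
  }
  invisible(path)
}

#' Read gene sets from a GMT file
#'
#' Standard GMT dialect: one set per line, tab-separated
#' `name<TAB>description<TAB>member...`.
#'
#' @param path Path to a `.gmt` file.
#' @return Named list of character vectors (set members).
#' @export
read_gene_sets <- function(path) {
  if (!file.exists(path)) stopf("GMT file not found: %s", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- lapply(seq_along(lines), function(i) {
    parts <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(parts) < 3)
      stopf("GMT line %d has no members (need name, description, members...)", i)
    members <- parts[-(1:2)]
    if (anyDuplicated(members))
      stopf("GMT line %d (%s) contains duplicate members", i, parts[1])
    members
  })
  names(sets) <- vapply(lines, function(l) strsplit(l, "\t", fixed = TRUE)[[1]][1], "")
  if (anyDuplicated(names(sets))) stopf("duplicate gene-set names in %s", path)
  sets
}

#' Packaged tumor-microenvironment archetype marker sets
#'
#' The three TME archetype marker gene lists (LN: lymph node-like, FMAC:
#' follicular macrophage and accessory cell, TEX: T-cell exhausted) shipped
#' with the package. The FMAC list carries the token `"CLEC14 CD36"` exactly
#' as printed in its source; whether it denotes one gene or two is ambiguous,
#' so it is kept verbatim (giving FMAC 19 members).
#'
#' @return Named list with elements `LN`, `FMAC`, `TEX`.
#' @export
archetype_gene_sets <- function() {
  read_gene_sets(system.file("extdata", "tme_archetypes.gmt",
                             package = "cfrnatme", mustWork = TRUE))
}

#' Read a sample metadata table
#'
#' @param path TSV with mandatory columns `sample_id`, `cohort`, `timepoint`,
#'   `response`, `pfs_time`, `pfs_event`, `intron_exon_ratio`,
#'   `five_three_bias`, `total_counts`. Extra columns are preserved.
#' @return data.frame, one row per sample.
#' @export
read_sample_metadata <- function(path) {
  meta <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  validate_sample_metadata(meta)
}

#' @rdname read_sample_metadata
#' @param meta In-memory metadata data.frame to validate.
#' @export
validate_sample_metadata <- function(meta) {
  required <- c("sample_id", "cohort", "timepoint", "response", "pfs_time",
                "pfs_event", "intron_exon_ratio", "five_three_bias",
                "total_counts")
  missing <- setdiff(required, names(meta))
  if (length(missing))
    stopf("metadata missing mandatory column(s): %s", paste(missing, collapse = ", "))
  if (anyDuplicated(meta$sample_id)) stopf("duplicate sample_id in metadata")
  if (any(meta$pfs_time < 0, na.rm = TRUE)) stopf("pfs_time must be >= 0")
  meta
}

#' Write a sample metadata table
#' @param meta Metadata data.frame.
#' @param path Output TSV path.
#' @export
write_sample_metadata <- function(meta, path) {
  write.table(meta, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
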