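#' Pipeline configuration
#'
#' Bundles inputs and per-stage settings for [run_full_pipeline()]. Inputs
#' may be file paths (`counts_path`, `metadata_path`, `gmt_path`) or
#' in-memory objects (`counts`, `metadata`, `gene_sets`); paths are validated
#' up front, before any compute.
#'
#' @param counts,metadata,gene_sets In-memory inputs (optional).
#' @param counts_path,metadata_path,gmt_path File inputs (optional).
#' @param qc A [qc_thresholds()].
#' @param norm A [norm_config()].
#' @param scoring A [scoring_config()].
#' @param cv A [cv_config()].
#' @param feature_sets Character vector of CV feature sets: gene-set names
#'   and/or `"all"`.
#' @param survival_set Gene-set name whose scaled score drives the median
#'   split (default `"LN"`).
#' @param discovery_cohorts,validation_cohort Cohort labels for the
#'   differential discovery/validation design.
#' @param adj_p_threshold BH threshold for the concordance join (default 0.1).
#' @param seed Global integer seed; stage substreams derive from it.
#' @param outdir Output directory (optional; created if given).
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(counts = NULL, metadata = NULL, gene_sets = NULL,
                            counts_path = NULL, metadata_path = NULL,
                            gmt_path = NULL,
                            qc = qc_thresholds(), norm = norm_config(),
                            scoring = scoring_config(), cv = cv_config(),
                            feature_sets = c("LN", "FMAC", "TEX", "all"),
                            survival_set = "LN",
                            discovery_cohorts = c("cohort1", "cohort2"),
                            validation_cohort = "cohort3",
                            adj_p_threshold = 0.1,
                            seed = 1L, outdir = NULL) {
  for (p in c(counts_path, metadata_path, gmt_path))
    if (!is.null(p) && !file.exists(p)) stopf("input file not found: %s", p)
  if (is.null(counts) && is.null(counts_path)) stopf("counts input required")
  if (is.null(metadata) && is.null(metadata_path)) stopf("metadata input required")
  structure(list(counts = counts, metadata = metadata, gene_sets = gene_sets,
                 counts_path = counts_path, metadata_path = metadata_path,
                 gmt_path = gmt_path, qc = qc, norm = norm, scoring = scoring,
                 cv = cv, feature_sets = feature_sets,
                 survival_set = survival_set,
                 discovery_cohorts = discovery_cohorts,
                 validation_cohort = validation_cohort,
                 adj_p_threshold = adj_p_threshold,
                 seed = as.integer(seed), outdir = outdir),
            class = "pipeline_config")
}

#' Run the full cfRNA analysis pipeline
#'
#' Sequences the six stages — QC filtering, TMM/log2-CPM normalization,
#' archetype module scoring, survival stratification, Monte Carlo
#' cross-validated classification, and differential abundance with
#' cross-cohort concordance — and returns a manifest recording the effective
#' configuration (hashed), seed, per-stage outputs and every warning emitted.
#'
#' @param config A [pipeline_config()].
#' @return List of class `pipeline_manifest`.
#' @export
run_full_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  warnings_log <- character(0)
  collect <- function(expr, stage) {
    withCallingHandlers(
      tryCatch(expr, error = function(e)
        stopf("stage '%s' failed: %s", stage, conditionMessage(e))),
      warning = function(w) {
        warnings_log <<- unique(c(warnings_log,
                                  sprintf("[%s] %s", stage, conditionMessage(w))))
        invokeRestart("muffleWarning")
      })
  }

  counts <- config$counts %||% read_count_matrix(config$counts_path)
  metadata <- config$metadata %||% read_sample_metadata(config$metadata_path)
  metadata <- validate_sample_metadata(metadata)
  gene_sets <- config$gene_sets %||%
    (if (!is.null(config$gmt_path)) read_gene_sets(config$gmt_path)
     else archetype_gene_sets())

  # 1. QC
  qc_res <- collect(apply_qc_filters(metadata, config$qc), "qc")
  keep <- intersect(colnames(counts), qc_res$kept)
  counts_f <- counts[, keep, drop = FALSE]
  meta_f <- metadata[match(keep, metadata$sample_id), , drop = FALSE]

  # 2. Normalization
  norm <- collect(normalize_counts(counts_f, config$norm), "normalize")

  # 3. Module scoring
  scoring_cfg <- config$scoring
  scoring_cfg$seed <- derive_seed(config$seed, 30L)
  score_tab <- collect(score_archetypes(norm, gene_sets, scoring_cfg), "score")
  score_tests <- lapply(names(gene_sets), function(nm) {
    s <- score_tab$scores[[paste0(nm, "_scaled")]]
    r <- response_indicator(meta_f$response)
    collect(mann_whitney_u(s[r == 1], s[r == 0]), "score")
  })
  names(score_tests) <- names(gene_sets)

  # 4. Survival stratification on the configured archetype score
  s <- score_tab$scores[[paste0(config$survival_set, "_scaled")]]
  strata <- collect(median_split(setNames(s, meta_f$sample_id)), "survival")
  surv_res <- list(
    strata = strata,
    km = lapply(split(seq_along(strata), strata), function(idx)
      kaplan_meier(meta_f$pfs_time[idx], meta_f$pfs_event[idx])),
    logrank = collect(logrank_test(meta_f$pfs_time, meta_f$pfs_event, strata),
                      "survival"),
    cox_highlow = collect(
      cox_univariate(as.integer(strata == "high"), meta_f$pfs_time,
                     meta_f$pfs_event), "survival"),
    cox_score = collect(
      cox_univariate(s, meta_f$pfs_time, meta_f$pfs_event), "survival"))

  # 5. Monte Carlo cross-validated classification per feature set
  cv_out <- list()
  for (k in seq_along(config$feature_sets)) {
    fs <- config$feature_sets[k]
    cv_cfg <- config$cv
    cv_cfg$seed <- derive_seed(config$seed, 100L + k)
    feats <- if (identical(fs, "all")) "all" else gene_sets[[fs]]
    res <- collect(monte_carlo_cv(norm, meta_f$response, feats, cv_cfg), "cv")
    cv_out[[fs]] <- list(results = res, summary = summarize_cv(res),
                         recurrence = feature_recurrence(res))
  }

  # 6. Differential abundance: discovery cohorts vs validation cohort
  disc_ids <- meta_f$sample_id[meta_f$cohort %in% config$discovery_cohorts]
  val_ids <- meta_f$sample_id[meta_f$cohort %in% config$validation_cohort]
  diff_res <- NULL
  if (length(disc_ids) >= 6 && length(val_ids) >= 2) {
    norm_d <- collect(normalize_counts(counts_f[, disc_ids, drop = FALSE],
                                       config$norm), "differential")
    norm_v <- collect(normalize_counts(counts_f[, val_ids, drop = FALSE],
                                       config$norm), "differential")
    lab_d <- meta_f$response[match(disc_ids, meta_f$sample_id)]
    lab_v <- meta_f$response[match(val_ids, meta_f$sample_id)]
    tab <- collect(differential_abundance(norm_d, lab_d), "differential")
    val_fc <- collect(log2_fold_change(norm_v, lab_v), "differential")
    conc <- tryCatch(
      cross_cohort_concordance(tab, val_fc, config$adj_p_threshold),
      error = function(e) list(r = NA_real_, n_genes = 0L,
                               note = conditionMessage(e)))
    diff_res <- list(discovery = tab, validation_fc = val_fc,
                     concordance = conc,
                     n_significant = sum(tab$adjusted_p < config$adj_p_threshold))
  } else {
    warnings_log <- c(warnings_log,
                      "[differential] too few discovery/validation samples; stage skipped")
  }

  cfg_for_hash <- config[setdiff(names(config), c("counts", "metadata"))]
  manifest <- structure(list(
    config = config,
    config_hash = rlang::hash(cfg_for_hash),
    seed = config$seed,
    stages = c("qc", "normalize", "score", "survival", "cv",
               if (!is.null(diff_res)) "differential"),
    qc = qc_res, norm = norm, scores = score_tab, score_tests = score_tests,
    survival = surv_res, cv = cv_out, differential = diff_res,
    warnings = warnings_log
  ), class = "pipeline_manifest")

  if (!is.null(config$outdir)) write_pipeline_outputs(manifest, config$outdir)
  manifest
}

`%||%` <- function(a, b) if (is.null(a)) b else a

write_pipeline_outputs <- function(manifest, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  write.table(manifest$scores$scores, file.path(outdir, "module_scores.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(manifest$differential))
    write.table(manifest$differential$discovery,
                file.path(outdir, "differential_abundance.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  auc_summary <- lapply(manifest$cv, function(z)
    list(n_valid = z$summary$n_valid, median_auc = z$summary$median_auc))
  jsonlite::write_json(
    list(config_hash = manifest$config_hash, seed = manifest$seed,
         stages = manifest$stages, auc = auc_summary,
         warnings = manifest$warnings),
    file.path(outdir, "manifest.json"), auto_unbox = TRUE, digits = NA)
  invisible(outdir)
}

#' Summarize a completed pipeline run
#'
#' Builds the report tables: per-cohort QC summary, module score by response
#' with Mann-Whitney results, survival stratification results, AUC
#' distribution summaries per feature set, feature recurrence, and the top of
#' the differential table.
#'
#' @param manifest A `pipeline_manifest` from [run_full_pipeline()].
#' @return Named list of data.frames/lists (class `pipeline_report`).
#' @export
generate_report <- function(manifest) {
  needed <- c("qc", "normalize", "score", "survival", "cv")
  missing <- setdiff(needed, manifest$stages)
  if (length(missing))
    stopf("manifest incomplete; missing stage(s): %s",
          paste(missing, collapse = ", "))
  meta <- manifest$config$metadata
  qc_summary <- NULL
  if (!is.null(meta)) {
    disc <- meta$sample_id %in% manifest$qc$discarded
    qc_summary <- as.data.frame(table(cohort = meta$cohort,
                                      status = ifelse(disc, "discarded", "kept")))
  }
  score_summary <- do.call(rbind, lapply(names(manifest$score_tests), function(nm)
    data.frame(gene_set = nm,
               mw_u = manifest$score_tests[[nm]]$statistic,
               mw_p = manifest$score_tests[[nm]]$p_value)))
  auc_summary <- do.call(rbind, lapply(names(manifest$cv), function(nm) {
    a <- manifest$cv[[nm]]$summary
    data.frame(feature_set = nm, n_valid = a$n_valid,
               median_auc = a$median_auc,
               iqr_auc = IQR(a$auc))
  }))
  recurrence <- if ("all" %in% names(manifest$cv))
    head(manifest$cv[["all"]]$recurrence, 10)
  survival_summary <- data.frame(
    test = c("logrank", "cox_highlow", "cox_score"),
    statistic = c(manifest$survival$logrank$statistic,
                  manifest$survival$cox_highlow$statistic,
                  manifest$survival$cox_score$statistic),
    p_value = c(manifest$survival$logrank$p_value,
                manifest$survival$cox_highlow$p_value,
                manifest$survival$cox_score$p_value),
    effect = c(NA, manifest$survival$cox_highlow$effect_estimate,
               manifest$survival$cox_score$effect_estimate))
  differential_top <- if (!is.null(manifest$differential)) {
    d <- manifest$differential$discovery
    head(d[order(d$adjusted_p), ], 10)
  }
  structure(list(qc_summary = qc_summary, score_summary = score_summary,
                 survival_summary = survival_summary,
                 auc_summary = auc_summary, recurrence = recurrence,
                 differential_top = differential_top,
                 concordance = manifest$differential$concordance,
                 warnings = manifest$warnings),
            class = "pipeline_report")
}
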