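test_that("equal-frequency binning assigns ranks to bins deterministically", {
  m <- matrix(seq_len(25), 25, 2,
              dimnames = list(sprintf("G%02d", 1:25), c("S1", "S2")))
  bins <- bin_genes_by_expression(make_norm(m), 25)
  expect_equal(unname(bins), 1:25)  # one gene per bin in rank order

  m2 <- matrix(rnorm(100 * 4), 100, 4,
               dimnames = list(sprintf("G%03d", 1:100), sprintf("S%d", 1:4)))
  bins2 <- bin_genes_by_expression(make_norm(m2), 25)
  expect_true(all(table(bins2) == 4))
  # brute-force rank-and-cut oracle
  means <- rowMeans(m2)
  ord <- order(means, names(means))
  oracle <- integer(100)
  oracle[match(names(means)[ord], names(means))] <- ceiling((1:100) * 25 / 100)
  expect_equal(unname(bins2), oracle)

  expect_error(bin_genes_by_expression(make_norm(m), 30), "fewer genes")
})

test_that("control sampling matches the target count and seed protocol", {
  m <- matrix(rnorm(200 * 5), 200, 5,
              dimnames = list(sprintf("G%03d", 1:200), sprintf("S%d", 1:5)))
  norm <- make_norm(m)
  bins <- bin_genes_by_expression(norm, 25)
  targets <- sprintf("G%03d", 1:20)
  a <- sample_control_genes(targets, bins, 100, seed = 7)
  b <- sample_control_genes(targets, bins, 100, seed = 7)
  expect_length(a$controls, 2000)  # 20 targets x 100 controls
  expect_identical(a$controls, b$controls)

  # a bin holding only the target forces the control multiset onto it
  bins1 <- setNames(c(1L, rep(2L, 199)), names(bins))
  solo <- sample_control_genes("G001", bins1, 100, seed = 1)
  expect_equal(unique(solo$controls), "G001")
  s <- module_score(norm, "G001", solo$controls)
  expect_equal(unname(s), rep(0, 5))
})

test_that("absent target genes are skipped with a warning, empty set fatal", {
  m <- matrix(rnorm(50 * 3), 50, 3,
              dimnames = list(sprintf("G%02d", 1:50), sprintf("S%d", 1:3)))
  bins <- bin_genes_by_expression(make_norm(m), 5)
  expect_warning(res <- sample_control_genes(c("G01", "NOPE"), bins, 10, 1),
                 "NOPE")
  expect_equal(res$missing, "NOPE")
  expect_error(suppressWarnings(sample_control_genes("NOPE", bins, 10, 1)),
               "no target genes")
  expect_error(module_score(make_norm(m), "NOPE", "G01"), "empty effective")
})

test_that("raw module score is the target-minus-control mean difference", {
  # constant matrix: any target/control combination scores 0
  m <- matrix(3, 30, 4, dimnames = list(sprintf("G%02d", 1:30),
                                        sprintf("S%d", 1:4)))
  norm <- make_norm(m)
  bins <- bin_genes_by_expression(norm, 1)
  ctl <- sample_control_genes(sprintf("G%02d", 1:5), bins, 100, seed = 2)
  expect_equal(unname(module_score(norm, ctl$targets_used, ctl$controls)),
               rep(0, 4))
  # every target gene sits 1 logCPM above the control mean in sample A
  m2 <- m
  m2[1:5, 1] <- 4
  s <- module_score(make_norm(m2), sprintf("G%02d", 1:5),
                    sprintf("G%02d", 11:20))
  expect_equal(unname(s[1]), 1)
  expect_equal(unname(s[2]), 0)
})

test_that("module scores match the brute-force oracle exactly", {
  set.seed(31)
  m <- matrix(rnorm(200 * 12, mean = 5, sd = 2), 200, 12,
              dimnames = list(sprintf("G%03d", 1:200), sprintf("S%02d", 1:12)))
  norm <- make_norm(m)
  targets <- sprintf("G%03d", seq(5, 195, by = 10))
  bins <- bin_genes_by_expression(norm, 25)
  ctl <- sample_control_genes(targets, bins, 100, seed = 7)
  got <- module_score(norm, ctl$targets_used, ctl$controls)
  want <- module_score_oracle(m, targets, n_bins = 25, controls_per_gene = 100,
                              seed = 7)
  expect_equal(got, want, tolerance = 1e-12)
})

test_that("min-max rescaling and its degenerate rule", {
  expect_equal(rescale_unit(c(2, 4, 6)), c(0, 0.5, 1))
  expect_warning(out <- rescale_unit(rep(3, 4)), "constant")
  expect_equal(out, rep(0.5, 4))
  expect_error(rescale_unit(c(1, NA)), "non-finite")
  set.seed(3)
  x <- rnorm(20)
  y <- rescale_unit(x)
  expect_equal(range(y), c(0, 1))
  expect_equal(order(y), order(x))  # strictly monotone transform
})

test_that("raw scores are invariant to per-sample constant shifts", {
  set.seed(17)
  m <- matrix(rnorm(100 * 6), 100, 6,
              dimnames = list(sprintf("G%03d", 1:100), sprintf("S%d", 1:6)))
  shift <- matrix(rep(rnorm(6, sd = 5), each = 100), 100, 6)
  targets <- sprintf("G%03d", 1:10)
  bins <- bin_genes_by_expression(make_norm(m), 10)
  ctl <- sample_control_genes(targets, bins, 50, seed = 5)
  s1 <- module_score(make_norm(m), targets, ctl$controls)
  s2 <- module_score(make_norm(m + shift), targets, ctl$controls)
  expect_equal(s1, s2, tolerance = 1e-10)
})

test_that("exchangeable targets and controls give mean-zero raw scores", {
  set.seed(23)
  m <- matrix(rnorm(200 * 8), 200, 8,
              dimnames = list(sprintf("G%03d", 1:200), sprintf("S%d", 1:8)))
  norm <- make_norm(m)
  bins <- bin_genes_by_expression(norm, 10)
  # permutation distribution of the raw score under random target choice
  means <- replicate(200, {
    targets <- sample(rownames(m), 15)
    ctl <- sample_control_genes(targets, bins, 50,
                                seed = sample.int(1e6, 1))
    mean(module_score(norm, targets, ctl$controls))
  })
  expect_lt(abs(mean(means)), 3 * sd(means) / sqrt(length(means)))
})

test_that("score_archetypes scores all packaged sets on a synthetic cohort", {
  sim <- small_cohort(seed = 5)
  norm <- normalize_counts(sim$counts)
  tab <- suppressWarnings(
    score_archetypes(norm, archetype_gene_sets(), scoring_config(seed = 9)))
  expect_named(tab$scores, c("sample_id", "LN_raw", "LN_scaled", "FMAC_raw",
                             "FMAC_scaled", "TEX_raw", "TEX_scaled"))
  for (col in c("LN_scaled", "FMAC_scaled", "TEX_scaled")) {
    expect_gte(min(tab$scores[[col]]), 0)
    expect_lte(max(tab$scores[[col]]), 1)
  }
  # injected LN effect separates responders with high confidence
  r <- response_ind <- sim$metadata$response == "responder"
  mw <- mann_whitney_u(tab$scores$LN_scaled[r], tab$scores$LN_scaled[!r])
  expect_lt(mw$p_value, 0.01)
  expect_gt(median(tab$scores$LN_scaled[r]), median(tab$scores$LN_scaled[!r]))
})

test_that("null-effect simulations give uniform Mann-Whitney p on module scores", {
  ln_set <- archetype_gene_sets()["LN"]
  ps <- vapply(1:200, function(i) {
    cfg <- sim_config(n_genes = 600, n_samples_per_cohort = c(15L, 15L),
                      effect_log2fc = c(LN = 0, FMAC = 0, TEX = 0),
                      seed = 9000 + i)
    sim <- simulate_cohort(cfg)
    norm <- normalize_counts(sim$counts)
    tab <- suppressWarnings(
      score_archetypes(norm, ln_set, scoring_config(seed = 9000 + i)))
    r <- sim$metadata$response == "responder"
    mann_whitney_u(tab$scores$LN_scaled[r], tab$scores$LN_scaled[!r])$p_value
  }, numeric(1))
  ks <- suppressWarnings(stats::ks.test(ps, "punif"))
  expect_gt(ks$p.value, 0.01)
})
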