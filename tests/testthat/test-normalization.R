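test_that("TMM factors are exactly 1 for identical and uniformly scaled columns", {
  counts <- matrix(rep(c(5L, 10L, 20L, 40L, 80L), 4), ncol = 4,
                   dimnames = list(sprintf("G%d", 1:5), sprintf("S%d", 1:4)))
  expect_equal(unname(tmm_factors(counts)), rep(1, 4))

  # depth cancels inside M: a 10x deeper library still gets factor 1
  counts2 <- counts
  counts2[, 2] <- counts2[, 2] * 10L
  expect_equal(unname(tmm_factors(counts2)), rep(1, 4))
})

test_that("TMM factors match the from-scratch trimmed weighted mean", {
  set.seed(5)
  counts <- rand_counts(50, 4, seed = 5, lambda = 100)
  # plant a strongly shifted gene block in one sample
  counts[1:10, 2] <- counts[1:10, 2] * 8L
  f <- tmm_factors(counts)
  expect_equal(unname(f), unname(tmm_oracle(counts)), tolerance = 1e-10)
  expect_lt(abs(exp(mean(log(f))) - 1), 1e-12)
})

test_that("TMM errors when a sample shares no positive genes with the reference", {
  counts <- matrix(c(5L, 9L, 0L, 0L,
                     6L, 11L, 0L, 0L,
                     0L, 0L, 7L, 8L), nrow = 4,
                   dimnames = list(sprintf("G%d", 1:4), sprintf("S%d", 1:3)))
  expect_error(tmm_factors(counts), "shares no positively expressed genes")
})

test_that("log2-CPM follows the stated formula", {
  counts <- matrix(c(0L, 999L), 2, 1, dimnames = list(c("G1", "G2"), "S1"))
  # force effective library size 1e6 via explicit factor
  f <- setNames(1e6 / sum(counts), "S1")
  norm <- log2_cpm(counts, f)
  expect_equal(norm$logcpm["G1", 1], log2(0.5))
  expect_equal(norm$logcpm["G2", 1], log2(999.5), tolerance = 1e-12)
  expect_equal(log2(999.5), 9.9657, tolerance = 1e-4)
})

test_that("log2-CPM is monotone in counts and scale-invariant", {
  counts <- rand_counts(30, 5, seed = 9)
  norm <- normalize_counts(counts)
  ord <- order(counts[, 1])
  expect_true(all(diff(norm$logcpm[ord, 1]) >= 0))
  # doubling counts+pseudocount and the effective library leaves values fixed
  c1 <- matrix(c(10L, 90L), 2, 1, dimnames = list(c("A", "B"), "S1"))
  c2 <- matrix(c(20L, 180L), 2, 1, dimnames = list(c("A", "B"), "S1"))
  n1 <- log2_cpm(c1, setNames(1, "S1"), norm_config(pseudocount = 1))
  n2 <- log2_cpm(c2, setNames(1, "S1"), norm_config(pseudocount = 2))
  expect_equal(n1$logcpm, n2$logcpm)
})

test_that("pseudobulk sums cells and conserves total counts", {
  sc <- list(counts = matrix(c(1L, 3L, 2L, 4L), nrow = 2, byrow = FALSE,
                             dimnames = list(c("c1", "c2"), c("gA", "gB"))),
             sample = c("S1", "S1"), cluster = c("K1", "K1"))
  pb <- pseudobulk(sc)
  expect_equal(unname(pb$counts[, "S1|K1"]), c(4L, 6L))
  # mass conservation on a larger fixture
  cfg <- sim_config(n_genes = 80, seed = 41)
  sc2 <- simulate_single_cell(4, 3, 12, cfg)
  pb2 <- pseudobulk(sc2)
  expect_equal(sum(pb2$counts), sum(sc2$counts))
})

test_that("cluster exclusion applies the <10-cells-in->3-samples rule on boundaries", {
  cfg <- sim_config(n_genes = 40, seed = 43,
                    marker_gene_sets = list(LN = 1:3),
                    effect_log2fc = c(LN = 0))
  # cluster 2: 5 cells in 4 of 5 samples -> deficient in 4 > 3 -> excluded
  ncell <- matrix(20L, 5, 3)
  ncell[1:4, 2] <- 5L
  sc <- simulate_single_cell(5, 3, ncell, cfg)
  pb <- pseudobulk(sc)
  expect_equal(pb$excluded, "C02")
  # cluster with 9 cells in exactly 3 samples -> not more than 3 -> retained
  ncell2 <- matrix(20L, 5, 3)
  ncell2[1:3, 3] <- 9L
  sc2 <- simulate_single_cell(5, 3, ncell2, cfg)
  expect_length(pseudobulk(sc2)$excluded, 0)
})

test_that("variable-gene selection matches a brute-force variance sort", {
  norm <- make_norm(matrix(rnorm(100 * 8, sd = rep(seq(0.1, 2, length.out = 100), 8)),
                           100, 8, dimnames = list(sprintf("G%03d", 1:100),
                                                   sprintf("S%d", 1:8))))
  got <- select_variable_genes(norm, 20)
  v <- apply(norm$logcpm, 1, var)
  want <- names(sort(v, decreasing = TRUE))[1:20]
  expect_setequal(got, want)
  # degenerate fixture: single varying gene
  m <- matrix(1, 5, 4, dimnames = list(sprintf("G%d", 1:5), sprintf("S%d", 1:4)))
  m[3, ] <- c(1, 2, 3, 4)
  expect_equal(select_variable_genes(make_norm(m), 1), "G3")
  expect_length(select_variable_genes(make_norm(m), 5), 5)
  expect_error(select_variable_genes(make_norm(m), 0), "positive")
})

test_that("PCA embedding agrees with a brute-force eigendecomposition", {
  set.seed(11)
  m <- matrix(rnorm(10 * 6), 10, 6,
              dimnames = list(sprintf("G%02d", 1:10), sprintf("S%d", 1:6)))
  res <- pca_embed(make_norm(m), n_components = 3)
  x <- scale(t(m), center = TRUE, scale = FALSE)
  eig <- eigen(crossprod(x) / (nrow(x) - 1))
  emb_oracle <- x %*% eig$vectors[, 1:3]
  for (k in 1:3) {
    s <- sign(sum(res$embedding[, k] * emb_oracle[, k]))
    expect_equal(unname(res$embedding[, k]), s * unname(emb_oracle[, k]),
                 tolerance = 1e-8)
  }
  expect_equal(res$explained_variance,
               (eig$values / sum(eig$values))[1:3], tolerance = 1e-8)
})

test_that("PCA contract: correlated genes, variance ordering, degeneracy", {
  m <- rbind(G1 = c(1, 2, 3, 4), G2 = c(2, 4, 6, 8))
  colnames(m) <- sprintf("S%d", 1:4)
  res <- pca_embed(make_norm(m), n_components = 1)
  expect_equal(res$explained_variance, 1)
  set.seed(13)
  m2 <- matrix(rnorm(40), 8, 5, dimnames = list(sprintf("G%d", 1:8),
                                                sprintf("S%d", 1:5)))
  r2 <- pca_embed(make_norm(m2), n_components = 4)
  expect_true(all(diff(r2$explained_variance) <= 1e-12))
  expect_lte(sum(r2$explained_variance), 1 + 1e-12)
  m3 <- matrix(5, 4, 3, dimnames = list(sprintf("G%d", 1:4), sprintf("S%d", 1:3)))
  expect_error(pca_embed(make_norm(m3)), "degenerate")
})

test_that("TMM agrees with edgeR on a random matrix", {
  skip_if_not_installed("edgeR")
  counts <- rand_counts(300, 6, seed = 17, lambda = 200)
  counts[1:30, 3] <- counts[1:30, 3] * 6L
  f <- tmm_factors(counts)
  f_edger <- edgeR::calcNormFactors(counts, method = "TMM")
  expect_equal(unname(f), unname(f_edger), tolerance = 0.02)
})
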