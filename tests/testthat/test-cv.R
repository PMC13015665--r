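test_that("stratified split uses round-half-up class arithmetic", {
  set.seed(1)
  y <- rep(c(0, 1), each = 10)
  sp <- stratified_split(y, 0.7)
  expect_equal(sum(y[sp$train] == 0), 7)
  expect_equal(sum(y[sp$train] == 1), 7)
  expect_equal(length(sp$test), 6)
  # disjoint and exhaustive
  expect_setequal(c(sp$train, sp$test), seq_along(y))
  expect_length(intersect(sp$train, sp$test), 0)
  # class of size 3 at 0.7: round(2.1) = 2 train, 1 test
  y2 <- c(rep(0, 10), rep(1, 3))
  sp2 <- stratified_split(y2, 0.7)
  expect_equal(sum(y2[sp2$train] == 1), 2)
  expect_equal(sum(y2[sp2$test] == 1), 1)
  # class too small to appear in both partitions
  expect_error(stratified_split(c(0, 0, 0, 1), 0.7), "too small")
})

test_that("AUC equals the exhaustive pair count with half-weight ties", {
  expect_equal(auc(c(1, 2, 3, 10, 11, 12), c(0, 0, 0, 1, 1, 1)), 1)
  expect_equal(auc(rep(5, 8), rep(c(0, 1), 4)), 0.5)
  set.seed(3)
  s <- sample(1:5, 8, replace = TRUE)  # forces ties
  y <- c(0, 1, 0, 1, 1, 0, 0, 1)
  pairs <- expand.grid(p = which(y == 1), n = which(y == 0))
  oracle <- mean(ifelse(s[pairs$p] > s[pairs$n], 1,
                        ifelse(s[pairs$p] == s[pairs$n], 0.5, 0)))
  expect_equal(auc(s, y), oracle, tolerance = 1e-12)
  expect_error(auc(1:4, rep(1, 4)), "single class")
})

test_that("AUC is the normalized Mann-Whitney U on random inputs", {
  set.seed(5)
  for (i in 1:10) {
    y <- rbinom(30, 1, 0.5)
    if (length(unique(y)) < 2) next
    s <- rnorm(30)
    u <- mann_whitney_u(s[y == 1], s[y == 0])$statistic
    expect_equal(auc(s, y), u / (sum(y == 1) * sum(y == 0)), tolerance = 1e-12)
  }
})

test_that("lasso satisfies the null KKT condition at large lambda", {
  set.seed(7)
  x <- matrix(rnorm(60 * 5), 60, 5, dimnames = list(NULL, paste0("f", 1:5)))
  y <- rbinom(60, 1, 0.5)
  std <- scale(x)
  lam_null <- max(abs(crossprod(std, y - mean(y)))) / nrow(x)
  fit <- fit_lasso_logistic(x, y, lambda = lam_null * 1.05)
  expect_true(all(fit$beta == 0))
  expect_equal(fit$intercept, qlogis(mean(y)), tolerance = 1e-6)
})

test_that("lasso at vanishing lambda matches an unpenalized Newton fit", {
  set.seed(9)
  x <- matrix(rnorm(200 * 2), 200, 2, dimnames = list(NULL, c("a", "b")))
  eta <- 0.8 * x[, 1] - 0.5 * x[, 2]
  y <- rbinom(200, 1, plogis(eta))
  fit <- fit_lasso_logistic(x, y, lambda = 1e-7, standardize = FALSE)
  ref <- glm(y ~ x, family = binomial())
  expect_equal(unname(fit$beta), unname(coef(ref)[2:3]), tolerance = 1e-4)
  expect_equal(fit$intercept, unname(coef(ref)[1]), tolerance = 1e-4)
})

test_that("KKT conditions hold at the returned solution", {
  set.seed(11)
  x <- matrix(rnorm(80 * 6), 80, 6, dimnames = list(NULL, paste0("f", 1:6)))
  y <- rbinom(80, 1, plogis(x[, 1]))
  lambda <- 0.05
  fit <- fit_lasso_logistic(x, y, lambda, standardize = TRUE)
  std <- cfrnatme:::standardize_features(x, TRUE)
  p <- plogis(drop(std$x %*% fit$beta) + fit$intercept)
  grad <- crossprod(std$x, p - y) / nrow(x)  # gradient of mean NLL
  active <- fit$beta != 0
  expect_true(all(abs(grad[active] + lambda * sign(fit$beta[active])) < 1e-5))
  expect_true(all(abs(grad[!active]) <= lambda + 1e-5))
})

test_that("non-zero count is non-increasing in lambda on a designed fixture", {
  set.seed(13)
  x <- matrix(rnorm(100 * 5), 100, 5, dimnames = list(NULL, paste0("f", 1:5)))
  y <- rbinom(100, 1, plogis(1.5 * x[, 1] + 1.0 * x[, 2] + 0.5 * x[, 3]))
  lams <- 10^seq(-3, 0, length.out = 15)
  nz <- vapply(lams, function(l)
    sum(fit_lasso_logistic(x, y, l)$beta != 0), numeric(1))
  expect_true(all(diff(nz) <= 0))
})

test_that("inner CV selects lambda by held-out AUC with ties toward sparsity", {
  set.seed(15)
  x <- matrix(rnorm(60 * 4), 60, 4, dimnames = list(NULL, paste0("f", 1:4)))
  y <- rbinom(60, 1, plogis(2 * x[, 1]))
  single <- inner_cv_select_lambda(x, y, cv_config(lambda_grid = 0.1))
  expect_equal(single$lambda, 0.1)
  sel <- inner_cv_select_lambda(x, y, cv_config(seed = 1))
  expect_true(sel$lambda %in% cv_config()$lambda_grid)
  # the informative feature survives at the selected lambda
  fit <- fit_lasso_logistic(x, y, sel$lambda)
  expect_true(fit$beta["f1"] != 0)
})

test_that("monte_carlo_cv records the configured number of reproducible iterations", {
  sim <- small_cohort(seed = 21, n_genes = 300)
  norm <- normalize_counts(sim$counts)
  cfg <- cv_config(n_iterations = 15, seed = 5)
  ln <- archetype_gene_sets()$LN
  a <- monte_carlo_cv(norm, sim$metadata$response, ln, cfg)
  b <- monte_carlo_cv(norm, sim$metadata$response, ln, cfg)
  expect_length(a, 15)
  expect_identical(lapply(a, `[[`, "auc"), lapply(b, `[[`, "auc"))
  expect_identical(lapply(a, `[[`, "nonzero"), lapply(b, `[[`, "nonzero"))
  s <- summarize_cv(a)
  expect_equal(s$n_valid, 15)
  expect_true(all(s$auc >= 0 & s$auc <= 1))
  # per-iteration AUC equals normalized U of the recorded test scores
  it <- a[[3]]
  lab <- sim$metadata$response[match(names(it$test_scores),
                                     sim$metadata$sample_id)]
  u <- mann_whitney_u(it$test_scores[lab == "responder"],
                      it$test_scores[lab != "responder"])$statistic
  expect_equal(it$auc, u / (sum(lab == "responder") * sum(lab != "responder")),
               tolerance = 1e-12)
})

test_that("feature recurrence reports frequencies at printed precision", {
  mk <- function(i, feats) list(iteration = i, auc = 0.7, lambda = 0.1,
                                nonzero = setNames(rep(0.2, length(feats)), feats),
                                test_scores = numeric(0), valid = TRUE)
  results <- lapply(1:101, function(i)
    mk(i, c(if (i <= 85) "IGHD", if (i <= 79) "SPDYC", "ALWAYS")))
  fr <- feature_recurrence(structure(results, class = "cv_results"))
  expect_equal(fr$selection_frequency[fr$feature == "IGHD"] * 100, 84.2,
               tolerance = 0.05)  # 85 of 101 models
  expect_equal(fr$selection_frequency[fr$feature == "ALWAYS"], 1)
  expect_equal(fr$feature[1], "ALWAYS")
  # a never-selected feature simply does not appear (frequency 0)
  expect_false("GHOST" %in% fr$feature)
})
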