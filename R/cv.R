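#' Monte Carlo cross-validation configuration
#'
#' Defaults mirror the modeling protocol: 101 Monte Carlo iterations,
#' 70%/30% response-stratified train/test splits, 5-fold inner
#' cross-validation for the L1 penalty, features standardized with train-set
#' statistics only.
#'
#' @param n_iterations Monte Carlo iterations (default 101).
#' @param train_fraction Training fraction per class (default 0.70,
#'   round-half-up per class).
#' @param inner_folds Inner CV folds for lambda selection (default 5).
#' @param lambda_grid Candidate penalty strengths: lambda multiplying the L1
#'   penalty added to the per-sample mean negative log-likelihood (default 30
#'   values log-spaced over `[1e-3, 1e2]`).
#' @param standardize Standardize features on train-fold mean/SD (default
#'   TRUE).
#' @param min_detect_fraction For the all-transcript feature set, keep genes
#'   with a non-zero count proportion of at least this in the training data
#'   (default 0.25); keeps the optimization well-posed.
#' @param seed Integer seed; iteration i uses a substream keyed by
#'   `(seed, i)` so serial and parallel execution agree.
#' @return List of class `cv_config`.
#' @export
cv_config <- function(n_iterations = 101L, train_fraction = 0.70,
                      inner_folds = 5L,
                      lambda_grid = 10^seq(-3, 2, length.out = 30),
                      standardize = TRUE, min_detect_fraction = 0.25,
                      seed = 1L) {
  if (train_fraction <= 0 || train_fraction >= 1)
    stopf("train_fraction must lie in (0, 1)")
  if (n_iterations < 1) stopf("n_iterations must be >= 1")
  if (any(lambda_grid <= 0)) stopf("lambda grid must be positive")
  structure(list(n_iterations = as.integer(n_iterations),
                 train_fraction = train_fraction,
                 inner_folds = as.integer(inner_folds),
                 lambda_grid = sort(lambda_grid, decreasing = TRUE),
                 standardize = isTRUE(standardize),
                 min_detect_fraction = min_detect_fraction,
                 seed = as.integer(seed)),
            class = "cv_config")
}

#' Response-stratified train/test split
#'
#' Within each class, `round(train_fraction * n_class)` samples (round half
#' up) go to training, the remainder to test; both classes must end up
#' represented in both partitions.
#'
#' @param labels Binary vector (0/1 or two-level factor).
#' @param train_fraction Training fraction.
#' @return List with `train` and `test` integer index vectors (disjoint,
#'   exhaustive).
#' @export
stratified_split <- function(labels, train_fraction = 0.70) {
  y <- as.integer(as.factor(labels))
  if (length(unique(y)) != 2) stopf("labels must contain exactly two classes")
  train <- integer(0)
  for (cl in unique(y)) {
    idx <- which(y == cl)
    n_tr <- round_half_up(train_fraction * length(idx))
    if (n_tr < 1 || n_tr >= length(idx))
      stopf("class too small to appear in both partitions")
    train <- c(train, sample(idx, n_tr))
  }
  list(train = sort(train), test = sort(setdiff(seq_along(y), train)))
}

# Stratified fold assignment: within each class, shuffled cyclic fold ids.
stratified_folds <- function(y, k) {
  fold <- integer(length(y))
  for (cl in unique(y)) {
    idx <- sample(which(y == cl))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  if (any(tapply(y, fold, function(v) length(unique(v))) < 2))
    stopf("a fold lacks both classes; reduce inner_folds or enlarge the train set")
  fold
}

#' Area under the ROC curve
#'
#' Probability that a random positive outranks a random negative, ties
#' counted one half (the normalized Mann-Whitney U).
#'
#' @param scores Predicted scores.
#' @param labels Binary labels (positives = second factor level or 1).
#' @return AUC in `[0, 1]`.
#' @export
auc <- function(scores, labels) {
  y <- as.integer(as.factor(labels)) - 1L
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  if (n1 == 0 || n0 == 0) stopf("AUC undefined: test set has a single class")
  r <- rank(scores)
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' L1-penalized logistic regression at a fixed penalty
#'
#' Minimizes the per-sample mean negative log-likelihood plus
#' `lambda * sum(|beta|)` (intercept unpenalized) by cyclic coordinate
#' descent (via glmnet). Optionally standardizes features first with the
#' supplied (train-set) statistics.
#'
#' @param x Samples x features numeric matrix.
#' @param y Binary labels.
#' @param lambda Penalty strength.
#' @param standardize Standardize columns to mean 0, SD 1 before fitting;
#'   coefficients are reported on the fitting scale, alongside the centers
#'   and scales used.
#' @return List with `beta` (named coefficients on the fitting scale),
#'   `intercept`, `lambda`, `center`, `scale`.
#' @export
fit_lasso_logistic <- function(x, y, lambda, standardize = TRUE) {
  if (!all(is.finite(x))) stopf("non-finite feature values")
  y <- as.integer(as.factor(y)) - 1L
  std <- standardize_features(x, standardize)
  # warm-started path down to the target lambda for solver accuracy
  lam_path <- sort(unique(c(lambda * c(64, 16, 4), lambda)), decreasing = TRUE)
  fit <- glmnet::glmnet(std$x, y, family = "binomial", alpha = 1,
                        lambda = lam_path, standardize = FALSE,
                        thresh = 1e-12, maxit = 1e6)
  k <- length(lam_path)
  beta <- as.numeric(fit$beta[, k])
  names(beta) <- colnames(x)
  list(beta = beta, intercept = fit$a0[[k]], lambda = lambda,
       center = std$center, scale = std$scale)
}

standardize_features <- function(x, standardize, center = NULL, scale = NULL) {
  if (!standardize)
    return(list(x = x, center = rep(0, ncol(x)), scale = rep(1, ncol(x))))
  if (is.null(center)) center <- colMeans(x)
  if (is.null(scale)) {
    scale <- apply(x, 2, sd)
    scale[scale == 0] <- 1
  }
  list(x = sweep(sweep(x, 2, center), 2, scale, "/"), center = center,
       scale = scale)
}

predict_lasso <- function(model, x_new, standardize = TRUE) {
  std <- standardize_features(x_new, standardize, model$center, model$scale)
  drop(std$x %*% model$beta) + model$intercept
}

#' Inner cross-validated penalty selection
#'
#' Stratified k-fold partition of the training data; for each fold a full
#' regularization path is fit on the remaining folds and held-out AUC is
#' computed per candidate lambda. Returns the lambda maximizing mean held-out
#' AUC, ties broken toward the larger (sparser) lambda.
#'
#' @param x Train samples x features matrix.
#' @param y Train labels.
#' @param config A [cv_config()].
#' @return List with `lambda` (selected), `mean_auc` (per candidate).
#' @export
inner_cv_select_lambda <- function(x, y, config = cv_config()) {
  y <- as.integer(as.factor(y)) - 1L
  lam <- config$lambda_grid
  if (length(lam) == 1) return(list(lambda = lam, mean_auc = NA_real_))
  fold <- stratified_folds(y, config$inner_folds)
  aucs <- matrix(NA_real_, config$inner_folds, length(lam))
  for (f in seq_len(config$inner_folds)) {
    tr <- fold != f
    std <- standardize_features(x[tr, , drop = FALSE], config$standardize)
    fit <- glmnet::glmnet(std$x, y[tr], family = "binomial", alpha = 1,
                          lambda = lam, standardize = FALSE, thresh = 1e-9,
                          maxit = 1e6)
    x_te <- standardize_features(x[!tr, , drop = FALSE], config$standardize,
                                 std$center, std$scale)$x
    pred <- predict(fit, newx = x_te, s = lam)
    aucs[f, ] <- apply(pred, 2, auc, labels = y[!tr])
  }
  mean_auc <- colMeans(aucs)
  best <- which(mean_auc == max(mean_auc))
  list(lambda = lam[best[1]], mean_auc = mean_auc)  # grid sorted decreasing
}

#' Monte Carlo cross-validated LASSO classification
#'
#' For each of `n_iterations` iterations: response-stratified 70/30 split,
#' inner-CV lambda selection on the training set, refit on the full training
#' set at the selected lambda, scoring of the held-out test set. Records test
#' AUC, selected lambda, non-zero coefficients and test-set predicted scores
#' per iteration. Iteration-level RNG is keyed by `(seed, iteration)` so
#' results are reproducible and order-independent.
#'
#' @param norm A `norm_matrix`.
#' @param labels Binary response labels, one per sample (matrix column).
#' @param feature_set Character vector of gene identifiers, or `"all"` for
#'   every gene passing the minimum-detection filter (non-zero log-CPM
#'   variation and detected in at least `min_detect_fraction` of training
#'   samples — applied per iteration on the training partition).
#' @param config A [cv_config()].
#' @return Object of class `cv_results`: list of per-iteration records
#'   (`iteration`, `auc`, `lambda`, `nonzero` named coefficient vector,
#'   `test_scores`, `valid`).
#' @export
monte_carlo_cv <- function(norm, labels, feature_set = "all",
                           config = cv_config()) {
  x_all <- t(norm$logcpm)
  detected_mat <- NULL
  if (identical(feature_set, "all")) {
    genes <- colnames(x_all)
    # a count of zero maps to log2(pseudocount * 1e6 / eff_j): anything
    # strictly above that level means the gene was detected in that sample
    zero_level <- log2(norm$pseudocount * 1e6 /
                         (norm$lib_sizes * norm$factors[colnames(norm$logcpm)]))
    detected_mat <- t(sweep(norm$logcpm, 2, zero_level) > 1e-9)
  } else {
    genes <- intersect(feature_set, colnames(x_all))
    if (!length(genes)) stopf("feature set is empty after intersecting with matrix genes")
  }
  y <- as.integer(as.factor(labels)) - 1L
  if (length(y) != nrow(x_all)) stopf("one label per sample required")

  results <- vector("list", config$n_iterations)
  for (i in seq_len(config$n_iterations)) {
    set.seed(derive_seed(config$seed, i))
    rec <- tryCatch({
      sp <- stratified_split(y, config$train_fraction)
      feats <- genes
      if (identical(feature_set, "all")) {
        # detection filter on the training partition only (no test leakage)
        frac <- colMeans(detected_mat[sp$train, , drop = FALSE])
        feats <- colnames(x_all)[frac >= config$min_detect_fraction]
      }
      x_tr <- x_all[sp$train, feats, drop = FALSE]
      x_te <- x_all[sp$test, feats, drop = FALSE]
      sel <- inner_cv_select_lambda(x_tr, y[sp$train], config)
      model <- fit_lasso_logistic(x_tr, y[sp$train], sel$lambda,
                                  standardize = config$standardize)
      scores <- predict_lasso(model, x_te, standardize = config$standardize)
      nz <- model$beta[model$beta != 0]
      list(iteration = i, auc = auc(scores, y[sp$test]), lambda = sel$lambda,
           nonzero = nz, test_scores = setNames(scores, rownames(x_te)),
           valid = TRUE)
    }, error = function(e)
      list(iteration = i, auc = NA_real_, lambda = NA_real_,
           nonzero = numeric(0), test_scores = numeric(0), valid = FALSE,
           error = conditionMessage(e)))
    results[[i]] <- rec
  }
  structure(results, class = "cv_results")
}

#' Summarize a Monte Carlo CV run
#' @param results A `cv_results` object.
#' @return List with `n_valid`, `median_auc`, `auc` vector.
#' @export
summarize_cv <- function(results) {
  valid <- vapply(results, `[[`, logical(1), "valid")
  aucs <- vapply(results[valid], `[[`, numeric(1), "auc")
  list(n_valid = sum(valid), median_auc = median(aucs), auc = aucs)
}

#' Feature recurrence across CV iterations
#'
#' Per feature: fraction of valid iterations with a non-zero coefficient,
#' plus median, IQR and sign consistency of its non-zero coefficients.
#' Sorted by decreasing frequency, ties by identifier.
#'
#' @param results A `cv_results` object.
#' @return data.frame with `feature`, `selection_frequency`,
#'   `coef_median`, `coef_iqr`, `sign_consistency`.
#' @export
feature_recurrence <- function(results) {
  valid <- Filter(function(r) isTRUE(r$valid), results)
  if (!length(valid)) stopf("no valid iterations")
  n <- length(valid)
  coefs <- list()
  for (r in valid) for (f in names(r$nonzero))
    coefs[[f]] <- c(coefs[[f]], r$nonzero[[f]])
  if (!length(coefs))
    return(data.frame(feature = character(0), selection_frequency = numeric(0),
                      coef_median = numeric(0), coef_iqr = numeric(0),
                      sign_consistency = numeric(0)))
  tab <- data.frame(
    feature = names(coefs),
    selection_frequency = vapply(coefs, length, integer(1)) / n,
    coef_median = vapply(coefs, median, numeric(1)),
    coef_iqr = vapply(coefs, IQR, numeric(1)),
    sign_consistency = vapply(coefs, function(v) max(mean(v > 0), mean(v < 0)),
                              numeric(1)),
    row.names = NULL
  )
  tab[order(-tab$selection_frequency, tab$feature), , drop = FALSE]
}
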