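#' Mann-Whitney U test (two-sided)
#'
#' Default group-comparison statistic of the pipeline. The U statistic uses
#' midranks for ties; the p-value is from exact enumeration when
#' `n1 * n2 <= 64` and there are no ties, and otherwise from the normal
#' approximation with tie correction and continuity correction.
#'
#' @param x,y Numeric vectors (the two groups).
#' @return List of class `test_result`: `statistic` (U for `x`), `p_value`,
#'   `method`, `effect_estimate` (U).
#' @export
mann_whitney_u <- function(x, y) {
  if (!length(x) || !length(y)) stopf("both groups must be non-empty")
  ties <- anyDuplicated(c(x, y)) > 0
  exact <- (length(x) * length(y) <= 64) && !ties
  res <- suppressWarnings(
    wilcox.test(x, y, alternative = "two.sided", exact = exact,
                correct = TRUE))
  structure(list(statistic = unname(res$statistic),
                 p_value = res$p.value,
                 method = if (exact) "mann_whitney_exact" else "mann_whitney_normal",
                 effect_estimate = unname(res$statistic)),
            class = "test_result")
}

#' Median split of a score vector
#'
#' Samples strictly above the median are labeled `"high"`, those at or below
#' `"low"` (even-n median is the midpoint of the two central order
#' statistics). Ties at the median go to `"low"`, matching the asymmetric
#' stratification rule "above median (high) and below-median (low)".
#'
#' @param scores Numeric vector (length >= 2).
#' @return Character vector of `"high"`/`"low"` labels.
#' @export
median_split <- function(scores) {
  if (length(scores) < 2) stopf("need at least 2 samples to stratify")
  if (length(unique(scores)) == 1)
    stopf("all scores identical: no median stratification possible")
  m <- median(scores)
  setNames(ifelse(scores > m, "high", "low"), names(scores))
}

#' Kaplan-Meier product-limit estimate
#'
#' @param time Non-negative event/censoring times.
#' @param event Binary event indicator (1 = progression/death observed).
#' @return data.frame with `time`, `n_risk`, `n_event`, `survival` at the
#'   observed event/censoring times, preceded by the origin row (t = 0,
#'   survival 1).
#' @export
kaplan_meier <- function(time, event) {
  if (any(time < 0)) stopf("times must be non-negative")
  fit <- survival::survfit(survival::Surv(time, event) ~ 1)
  data.frame(time = c(0, fit$time),
             n_risk = c(length(time), fit$n.risk),
             n_event = c(0, fit$n.event),
             survival = c(1, fit$surv))
}

#' Two-group log-rank test
#'
#' Chi-square statistic on 1 degree of freedom from observed minus expected
#' events across the distinct event times.
#'
#' @param time,event Survival record vectors.
#' @param group Two-level group labels.
#' @return `test_result` with the chi-square statistic and two-sided p.
#' @export
logrank_test <- function(time, event, group) {
  g <- as.factor(group)
  if (nlevels(g) != 2 || any(table(g) == 0)) stopf("need two non-empty groups")
  if (sum(event) == 0) stopf("no events observed: log-rank test undefined")
  fit <- survival::survdiff(survival::Surv(time, event) ~ g)
  structure(list(statistic = fit$chisq,
                 p_value = pchisq(fit$chisq, df = 1, lower.tail = FALSE),
                 method = "logrank",
                 effect_estimate = unname((fit$obs / fit$exp)[1] /
                                            (fit$obs / fit$exp)[2])),
            class = "test_result")
}

# Cox partial log-likelihood, score and information for a single covariate
# with Breslow tie handling. Data must be ordered by time.
cox_quantities <- function(beta, time, event, x) {
  ord <- order(time)
  time <- time[ord]; event <- event[ord]; x <- x[ord]
  eta <- beta * x
  w <- exp(eta)
  # risk-set cumulative sums from the largest time backwards
  n <- length(time)
  rev_idx <- n:1
  s0 <- rev(cumsum(rev(w)))
  s1 <- rev(cumsum(rev(w * x)))
  s2 <- rev(cumsum(rev(w * x^2)))
  # Breslow: all events at a tied time share the risk set entered at the
  # first index of that time
  first_at_time <- match(time, time)
  s0 <- s0[first_at_time]; s1 <- s1[first_at_time]; s2 <- s2[first_at_time]
  d <- event == 1
  loglik <- sum(eta[d]) - sum(log(s0[d]))
  score <- sum(x[d] - s1[d] / s0[d])
  info <- sum(s2[d] / s0[d] - (s1[d] / s0[d])^2)
  list(loglik = loglik, score = score, info = info)
}

#' Univariate Cox proportional hazards regression
#'
#' Newton-Raphson maximization of the Cox partial likelihood with Breslow
#' tie handling; convergence when the absolute score falls below `tol` (at
#' most `max_iter` iterations). Reports the hazard ratio, Wald z and
#' two-sided p.
#'
#' @param x Numeric covariate (binary group indicator or continuous score).
#' @param time,event Survival record vectors.
#' @param tol Score-equation convergence tolerance (default 1e-8).
#' @param max_iter Maximum Newton iterations (default 50).
#' @return `test_result` with `statistic` (Wald z), `p_value`,
#'   `effect_estimate` (hazard ratio), plus `beta`, `se`, `score_residual`,
#'   `loglik`, `n_events`.
#' @export
cox_univariate <- function(x, time, event, tol = 1e-8, max_iter = 50L) {
  if (!all(is.finite(x))) stopf("covariate must be finite")
  if (var(x) == 0) stopf("constant covariate: hazard ratio not identifiable")
  if (sum(event) < 1) stopf("need at least one event")
  beta <- 0
  for (iter in seq_len(max_iter)) {
    q <- cox_quantities(beta, time, event, x)
    if (abs(q$score) < tol) break
    step <- q$score / q$info
    # damp absurd steps; divergence signals monotone partial likelihood
    if (!is.finite(step)) stopf("singular information matrix")
    beta <- beta + sign(step) * min(abs(step), 5)
    if (abs(beta) > 20)
      stopf("monotone partial likelihood (perfect risk separation): Cox fit does not converge")
  }
  q <- cox_quantities(beta, time, event, x)
  if (abs(q$score) >= tol)
    stopf("Cox Newton-Raphson did not converge in %d iterations", max_iter)
  se <- sqrt(1 / q$info)
  z <- beta / se
  structure(list(statistic = z,
                 p_value = 2 * pnorm(-abs(z)),
                 method = "cox_wald_breslow",
                 effect_estimate = exp(beta),
                 beta = beta, se = se,
                 score_residual = q$score,
                 loglik = q$loglik,
                 n_events = sum(event)),
            class = "test_result")
}

#' @export
print.test_result <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4g, p = %.4g, effect = %.4g\n",
              x$method, x$statistic, x$p_value, x$effect_estimate))
  invisible(x)
}
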