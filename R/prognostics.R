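#' Categorize a global brain abnormality score
#'
#' Maps the Kidokoro-style global abnormality total to its category:
#' 0-3 normal, 4-7 mild, 8-11 moderate, >= 12 severe.
#'
#' @param score integer vector of non-negative totals.
#' @return factor with levels normal, mild, moderate, severe.
#' @export
classify_global_abnormality <- function(score) {
  if (any(is.na(score)) || any(score < 0)) stop("scores must be non-negative")
  cut(score, breaks = c(-0.5, 3.5, 7.5, 11.5, Inf),
      labels = c("normal", "mild", "moderate", "severe"))
}

#' Dichotomize normalized DWMA at a percentile cut-off
#'
#' Flags values strictly above the cohort percentile (default the
#' pre-specified 90th), computed with linear interpolation between order
#' statistics. With all values equal nothing is flagged (strict
#' inequality).
#'
#' @param ndwma_values numeric vector of normalized DWMA volumes.
#' @param percentile cut-off percentile in (0, 100); default 90.
#' @param type quantile algorithm (see [stats::quantile()]); default 7,
#'   linear interpolation.
#' @return logical vector, `TRUE` = severe.
#' @export
dichotomize_severe <- function(ndwma_values, percentile = 90, type = 7) {
  if (length(ndwma_values) == 0) stop("empty value list")
  cut <- stats::quantile(ndwma_values, percentile / 100, type = type, names = FALSE)
  ndwma_values > cut
}

#' 2x2 contingency table of a binary predictor against a binary outcome
#'
#' Either supply the four counts directly, or two logical/0-1 vectors
#' (`predictor`, `outcome`) from which they are tallied.
#'
#' @param tp,fn,fp,tn counts: predictor positive/negative x outcome
#'   present/absent.
#' @param predictor,outcome optional logical vectors.
#' @return object of class `contingency_table`.
#' @export
contingency_table <- function(tp = NULL, fn = NULL, fp = NULL, tn = NULL,
                              predictor = NULL, outcome = NULL) {
  if (!is.null(predictor)) {
    predictor <- as.logical(predictor)
    outcome <- as.logical(outcome)
    if (length(predictor) != length(outcome)) stop("vector lengths differ")
    tp <- sum(predictor & outcome)
    fn <- sum(!predictor & outcome)
    fp <- sum(predictor & !outcome)
    tn <- sum(!predictor & !outcome)
  }
  counts <- c(tp = tp, fn = fn, fp = fp, tn = tn)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be non-negative integers")
  if (sum(counts) == 0) stop("table total must be > 0")
  structure(as.list(counts), class = "contingency_table")
}

#' @export
print.contingency_table <- function(x, ...) {
  m <- matrix(c(x$tp, x$fn, x$fp, x$tn), 2, 2,
              dimnames = list(predictor = c("positive", "negative"),
                              outcome = c("present", "absent")))
  print(m)
  invisible(x)
}

#' Exact (Clopper-Pearson) binomial confidence interval
#'
#' Lower bound is the alpha/2 Beta quantile with shapes (x, n - x + 1),
#' upper the 1 - alpha/2 quantile with shapes (x + 1, n - x); exactly 0
#' when x = 0 and exactly 1 when x = n.
#'
#' @param x number of successes.
#' @param n number of trials.
#' @param level confidence level (default 0.95).
#' @return numeric `c(lower, upper)`.
#' @export
exact_binomial_ci <- function(x, n, level = 0.95) {
  if (n <= 0 || x < 0 || x > n || x != round(x) || n != round(n))
    stop("need integer 0 <= x <= n with n > 0")
  a <- 1 - level
  lo <- if (x == 0) 0 else stats::qbeta(a / 2, x, n - x + 1)
  hi <- if (x == n) 1 else stats::qbeta(1 - a / 2, x + 1, n - x)
  c(lower = lo, upper = hi)
}

#' Two-sided Fisher's exact test for a 2x2 table
#'
#' Enumerates all tables consistent with the observed margins; the
#' two-sided p-value is the total hypergeometric probability of tables no
#' more probable than the observed one (probability-mass rule, with a
#' relative slack of 1e-7 against ties lost to rounding).
#'
#' @param table a [contingency_table()].
#' @return p-value.
#' @export
fisher_exact <- function(table) {
  if (!inherits(table, "contingency_table")) stop("`table` must be a contingency_table")
  m <- table$tp + table$fn          # outcome present
  n <- table$fp + table$tn          # outcome absent
  k <- table$tp + table$fp          # predictor positive
  support <- max(0, k - n):min(k, m)
  probs <- stats::dhyper(support, m, n, k)
  p_obs <- stats::dhyper(table$tp, m, n, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

#' Prognostic test properties of a 2x2 table
#'
#' Sensitivity and specificity with exact Clopper-Pearson intervals,
#' positive and negative likelihood ratios with standard log-method
#' intervals, and a two-sided Fisher's exact p-value. When specificity is
#' 1 the positive likelihood ratio is reported as +Inf, and when
#' sensitivity is 1 the negative ratio is 0; their intervals are then
#' one-sided.
#'
#' @param table a [contingency_table()].
#' @param level confidence level (default 0.95).
#' @return object of class `prognostic_properties`: lists `sensitivity`,
#'   `specificity`, `lr_pos`, `lr_neg` (each `estimate`, `lower`,
#'   `upper`), plus `fisher_p` and the `table`.
#' @export
prognostic_properties <- function(table, level = 0.95) {
  if (!inherits(table, "contingency_table")) stop("`table` must be a contingency_table")
  npos <- table$tp + table$fn
  nneg <- table$fp + table$tn
  if (npos == 0 || nneg == 0)
    stop("need at least one subject with and one without the outcome")
  sens <- table$tp / npos
  spec <- table$tn / nneg
  z <- stats::qnorm(1 - (1 - level) / 2)

  lr_ci <- function(est, a, n1, b, n2) {
    # log-method: SE of log LR from the 2x2 counts (a/n1) / (b/n2)
    if (!is.finite(est) || est <= 0 || a == 0 || b == 0)
      return(c(NA_real_, NA_real_))
    se <- sqrt(1 / a - 1 / n1 + 1 / b - 1 / n2)
    exp(log(est) + c(-1, 1) * z * se)
  }

  lrp <- if (spec < 1) sens / (1 - spec) else Inf
  lrn <- if (spec > 0) (1 - sens) / spec else Inf
  ci_lrp <- lr_ci(lrp, table$tp, npos, table$fp, nneg)
  ci_lrn <- lr_ci(lrn, table$fn, npos, table$tn, nneg)

  as_prop <- function(est, ci) list(estimate = est, lower = ci[[1]], upper = ci[[2]])
  structure(list(
    sensitivity = as_prop(sens, exact_binomial_ci(table$tp, npos, level)),
    specificity = as_prop(spec, exact_binomial_ci(table$tn, nneg, level)),
    lr_pos = as_prop(lrp, ci_lrp),
    lr_neg = as_prop(lrn, ci_lrn),
    fisher_p = fisher_exact(table),
    table = table,
    level = level
  ), class = "prognostic_properties")
}

#' @export
print.prognostic_properties <- function(x, ...) {
  pct <- function(p) sprintf("%.1f%% (%.1f%%, %.1f%%)",
                             100 * p$estimate, 100 * p$lower, 100 * p$upper)
  lr <- function(p) {
    if (!is.finite(p$estimate)) return("Inf")
    if (is.na(p$lower)) sprintf("%.2f", p$estimate)
    else sprintf("%.2f (%.2f, %.2f)", p$estimate, p$lower, p$upper)
  }
  cat("Prognostic test properties\n")
  cat("  sensitivity:", pct(x$sensitivity), "\n")
  cat("  specificity:", pct(x$specificity), "\n")
  cat("  LR+:        ", lr(x$lr_pos), "\n")
  cat("  LR-:        ", lr(x$lr_neg), "\n")
  cat(sprintf("  Fisher exact p: %.4g\n", x$fisher_p))
  invisible(x)
}

#' Cohen's kappa
#'
#' Chance-corrected agreement kappa = (p_o - p_e) / (1 - p_e), either from
#' the observed and expected agreement proportions directly, or from a
#' square confusion matrix (`cohen_kappa_table`), where p_o is the diagonal
#' proportion and p_e the sum of products of the marginal proportions.
#'
#' @param p_o observed agreement proportion.
#' @param p_e expected (chance) agreement proportion, in \[0, 1).
#' @return object of class `kappa_result`: `p_o`, `p_e`, `kappa`.
#' @export
cohen_kappa <- function(p_o, p_e) {
  if (p_e >= 1 || p_e < 0 || p_o < 0 || p_o > 1)
    stop("need 0 <= p_o <= 1 and 0 <= p_e < 1")
  structure(list(p_o = p_o, p_e = p_e, kappa = (p_o - p_e) / (1 - p_e)),
            class = "kappa_result")
}

#' @rdname cohen_kappa
#' @param confusion square numeric matrix of cross-rating counts.
#' @export
cohen_kappa_table <- function(confusion) {
  confusion <- as.matrix(confusion)
  if (nrow(confusion) != ncol(confusion)) stop("confusion matrix must be square")
  tot <- sum(confusion)
  if (tot <= 0) stop("confusion matrix is empty")
  p_o <- sum(diag(confusion)) / tot
  p_e <- sum(rowSums(confusion) * colSums(confusion)) / tot^2
  cohen_kappa(p_o, p_e)
}

#' @export
print.kappa_result <- function(x, ...) {
  cat(sprintf("Cohen's kappa: %.3f (observed agreement %.1f%%, expected %.1f%%)\n",
              x$kappa, 100 * x$p_o, 100 * x$p_e))
  invisible(x)
}

#' Ordinary least squares with classical inference
#'
#' Fits y = X b by least squares and reports coefficients, classical
#' standard errors, t-based confidence intervals, R-squared and adjusted
#' R-squared (1 - (1 - R^2)(n - 1)/(n - p - 1), p predictors beside the
#' intercept). `X` may be a design matrix (an intercept column is added
#' unless one is present) or a formula with `data`.
#'
#' @param X design matrix, or a formula.
#' @param y response vector, or (for a formula) a `data.frame`.
#' @param level confidence level (default 0.95).
#' @return object of class `regression_result`: `coefficients` data.frame
#'   (term, estimate, se, lower, upper, p), `r2`, `adj_r2`, `sigma`, `n`,
#'   `fit` (the underlying [stats::lm()] object).
#' @export
ols_fit <- function(X, y, level = 0.95) {
  if (inherits(X, "formula")) {
    fit <- stats::lm(X, data = y)
  } else {
    X <- as.matrix(X)
    if (!any(apply(X, 2, function(c) all(c == 1))))
      X <- cbind(`(Intercept)` = 1, X)
    if (qr(X)$rank < ncol(X)) stop("design matrix is rank deficient")
    if (nrow(X) <= ncol(X)) stop("need n > number of parameters")
    df <- as.data.frame(X[, colnames(X) != "(Intercept)", drop = FALSE])
    df$.y <- y
    fit <- stats::lm(.y ~ ., data = df)
  }
  s <- summary(fit)
  ci <- stats::confint(fit, level = level)
  co <- s$coefficients
  coefficients <- data.frame(term = rownames(co),
                             estimate = co[, 1],
                             se = co[, 2],
                             lower = ci[, 1],
                             upper = ci[, 2],
                             p = co[, 4],
                             row.names = NULL)
  structure(list(coefficients = coefficients,
                 r2 = s$r.squared,
                 adj_r2 = s$adj.r.squared,
                 sigma = s$sigma,
                 n = length(stats::residuals(fit)),
                 fit = fit),
            class = "regression_result")
}

#' Logistic regression with odds ratios
#'
#' Maximum-likelihood logistic regression (iteratively reweighted least
#' squares) reporting odds ratios with Wald intervals. Complete or
#' quasi-complete separation (fitted probabilities collapsing to 0/1 with
#' diverging coefficients) raises an error advising exact or penalized
#' methods.
#'
#' @param X design matrix (intercept added unless present), or a formula.
#' @param y binary response (0/1), or (for a formula) a `data.frame`.
#' @param level confidence level.
#' @return object of class `regression_result` whose `coefficients` carry
#'   log-odds estimates plus `or`, `or_lower`, `or_upper` columns.
#' @export
logistic_fit <- function(X, y, level = 0.95) {
  if (inherits(X, "formula")) {
    fit <- stats::glm(X, data = y, family = stats::binomial())
  } else {
    X <- as.matrix(X)
    if (!any(apply(X, 2, function(c) all(c == 1))))
      X <- cbind(`(Intercept)` = 1, X)
    yy <- as.numeric(y)
    if (length(unique(yy)) < 2) stop("both outcome classes must be present")
    df <- as.data.frame(X[, colnames(X) != "(Intercept)", drop = FALSE])
    df$.y <- yy
    fit <- withCallingHandlers(
      stats::glm(.y ~ ., data = df, family = stats::binomial(),
                 control = stats::glm.control(epsilon = 1e-8, maxit = 50)),
      warning = function(w) {
        if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
          invokeRestart("muffleWarning")
      })
  }
  if (length(unique(fit$y)) < 2) stop("both outcome classes must be present")
  perfect <- all(abs(fit$fitted.values - fit$y) < 1e-4)
  if (perfect || (max(abs(stats::coef(fit))) > 20 &&
                  (any(fit$fitted.values > 1 - 1e-8) ||
                   any(fit$fitted.values < 1e-8))))
    stop("complete or quasi-complete separation detected; ",
         "consider exact logistic regression or penalization")
  s <- summary(fit)
  z <- stats::qnorm(1 - (1 - level) / 2)
  co <- s$coefficients
  coefficients <- data.frame(term = rownames(co),
                             estimate = co[, 1],
                             se = co[, 2],
                             lower = co[, 1] - z * co[, 2],
                             upper = co[, 1] + z * co[, 2],
                             p = co[, 4],
                             row.names = NULL)
  coefficients$or <- exp(coefficients$estimate)
  coefficients$or_lower <- exp(coefficients$lower)
  coefficients$or_upper <- exp(coefficients$upper)
  structure(list(coefficients = coefficients,
                 r2 = NA_real_,
                 adj_r2 = NA_real_,
                 sigma = NA_real_,
                 n = length(fit$y),
                 fit = fit),
            class = "regression_result")
}

#' @export
print.regression_result <- function(x, ...) {
  co <- x$coefficients
  cat(sprintf("Regression on %d observations\n", x$n))
  print(data.frame(term = co$term,
                   estimate = signif(co$estimate, 4),
                   ci = sprintf("(%.4g, %.4g)", co$lower, co$upper),
                   p = signif(co$p, 3)), row.names = FALSE)
  if (!is.na(x$r2))
    cat(sprintf("R^2 = %.3f, adjusted R^2 = %.3f\n", x$r2, x$adj_r2))
  invisible(x)
}

#' @export
coef.regression_result <- function(object, ...) {
  stats::setNames(object$coefficients$estimate, object$coefficients$term)
}

#' Bias-corrected bootstrap confidence interval
#'
#' Nonparametric bootstrap interval with median-bias correction (BC): z0
#' is estimated from the fraction of bootstrap statistics below the point
#' estimate and the percentile levels are adjusted accordingly.
#' `method = "bca"` additionally estimates the acceleration constant by
#' jackknife (BCa). Deterministic given `seed`.
#'
#' @param sample numeric vector (or data.frame whose rows are resampled).
#' @param statistic function of a sample returning a scalar.
#' @param B number of bootstrap resamples (default 10000, minimum 1000).
#' @param level confidence level.
#' @param seed integer seed for the resampling.
#' @param method `"bc"` (default) or `"bca"`.
#' @return numeric `c(lower, upper)` with attribute `"estimate"`.
#' @export
bootstrap_bca_ci <- function(sample, statistic, B = 10000, level = 0.95,
                             seed = 1L, method = c("bc", "bca")) {
  method <- match.arg(method)
  n <- if (is.data.frame(sample)) nrow(sample) else length(sample)
  if (n < 10) stop("sample size must be >= 10")
  if (B < 1000) stop("B must be >= 1000")
  take <- if (is.data.frame(sample)) {
    function(i) sample[i, , drop = FALSE]
  } else {
    function(i) sample[i]
  }
  theta <- statistic(sample)
  thetas <- with_seed(seed, {
    vapply(seq_len(B),
           function(b) statistic(take(base::sample.int(n, n, replace = TRUE))),
           numeric(1))
  })
  if (all(thetas == thetas[1])) {
    warning("degenerate statistic: all bootstrap resamples identical")
    out <- c(lower = thetas[1], upper = thetas[1])
    attr(out, "estimate") <- theta
    return(out)
  }
  prop <- (sum(thetas < theta) + 0.5 * sum(thetas == theta)) / B
  prop <- min(max(prop, 1 / (2 * B)), 1 - 1 / (2 * B))
  z0 <- stats::qnorm(prop)
  a <- 0
  if (method == "bca") {
    jack <- vapply(seq_len(n), function(i) statistic(take(-i)), numeric(1))
    jm <- mean(jack)
    num <- sum((jm - jack)^3)
    den <- 6 * (sum((jm - jack)^2))^1.5
    a <- if (den > 0) num / den else 0
  }
  zl <- stats::qnorm((1 - level) / 2)
  zu <- -zl
  adj <- function(z) stats::pnorm(z0 + (z0 + z) / (1 - a * (z0 + z)))
  qs <- stats::quantile(thetas, c(adj(zl), adj(zu)), type = 7, names = FALSE)
  out <- c(lower = qs[1], upper = qs[2])
  attr(out, "estimate") <- theta
  out
}
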