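# The statistical evaluation layer: category coding, dichotomization,
# prognostic properties, exact CIs, Fisher's exact test, kappa, regression,
# bootstrap.

test_that("global abnormality categories honour the published boundaries", {
  got <- classify_global_abnormality(c(0, 3, 4, 7, 8, 11, 12, 25))
  expect_identical(as.character(got),
                   c("normal", "normal", "mild", "mild", "moderate",
                     "moderate", "severe", "severe"))
  expect_error(classify_global_abnormality(-1), "non-negative")
})

test_that("90th-percentile dichotomization is strict and matches a sort oracle", {
  x <- c(5, 1, 9, 3, 7, 2, 8, 4, 6, 10)
  flag <- dichotomize_severe(x)
  expect_equal(sum(flag), 1)           # 10 distinct values: exactly one above P90
  expect_true(flag[x == 10])
  expect_false(any(dichotomize_severe(rep(0.3, 25))))   # all equal: none
  # sort-based linear-interpolation oracle
  set.seed(4)
  for (rep in 1:10) {
    v <- rlnorm(sample(15:80, 1))
    h <- (length(v) - 1) * 0.9
    s <- sort(v)
    cut <- s[floor(h) + 1] + (h - floor(h)) * (s[floor(h) + 2] - s[floor(h) + 1])
    expect_identical(dichotomize_severe(v), v > cut)
  }
  expect_error(dichotomize_severe(numeric(0)), "empty")
})

test_that("prognostic properties reproduce the worked 2x2 examples", {
  # severe DWMA vs CP: 6 CP / 76 non-CP
  p1 <- prognostic_properties(contingency_table(4, 2, 4, 72))
  expect_equal(100 * p1$sensitivity$estimate, 66.7, tolerance = 0.05)
  expect_equal(100 * p1$specificity$estimate, 94.7, tolerance = 0.05)
  expect_equal(p1$lr_pos$estimate, 12.7, tolerance = 0.05)
  expect_equal(p1$lr_neg$estimate, 0.35, tolerance = 0.01)
  expect_lt(p1$fisher_p, 0.001)

  p2 <- prognostic_properties(contingency_table(3, 3, 3, 73))
  expect_equal(100 * p2$sensitivity$estimate, 50.0, tolerance = 0.05)
  expect_equal(100 * p2$specificity$estimate, 96.1, tolerance = 0.05)
  expect_equal(p2$lr_pos$estimate, 12.7, tolerance = 0.05)
  expect_equal(p2$lr_neg$estimate, 0.52, tolerance = 0.01)

  p3 <- prognostic_properties(contingency_table(1, 5, 10, 66))
  expect_equal(100 * p3$sensitivity$estimate, 16.7, tolerance = 0.05)
  expect_equal(100 * p3$specificity$estimate, 86.8, tolerance = 0.05)
  expect_equal(p3$lr_pos$estimate, 1.27, tolerance = 0.01)
  expect_equal(p3$lr_neg$estimate, 0.96, tolerance = 0.01)

  # perfect specificity: LR+ is infinite
  p4 <- prognostic_properties(contingency_table(3, 3, 0, 70))
  expect_identical(p4$lr_pos$estimate, Inf)
})

test_that("Clopper-Pearson bounds match printed values and tail equations", {
  ci1 <- exact_binomial_ci(4, 6)
  expect_equal(unname(ci1), c(0.223, 0.957), tolerance = 5e-4)
  ci2 <- exact_binomial_ci(1, 6)
  expect_equal(ci2[["lower"]], 0.0042, tolerance = 5e-3)
  expect_equal(ci2[["lower"]], 1 - 0.975^(1 / 6), tolerance = 1e-10)
  expect_identical(exact_binomial_ci(0, 9)[["lower"]], 0)
  expect_identical(exact_binomial_ci(9, 9)[["upper"]], 1)
  # defining tail equations: P(X >= x | p = lower) = alpha/2, and
  # P(X <= x | p = upper) = alpha/2
  for (case in list(c(4, 6), c(1, 6), c(7, 20), c(19, 20))) {
    x <- case[1]; n <- case[2]
    ci <- exact_binomial_ci(x, n)
    expect_equal(1 - pbinom(x - 1, n, ci[["lower"]]), 0.025, tolerance = 1e-9)
    expect_equal(pbinom(x, n, ci[["upper"]]), 0.025, tolerance = 1e-9)
  }
  expect_error(exact_binomial_ci(5, 4), "x")
})

# independent enumeration oracle computing table probabilities from
# log-binomial coefficients directly
fisher_oracle <- function(tp, fn, fp, tn) {
  m <- tp + fn; n2 <- fp + tn; k <- tp + fp; N <- m + n2
  supp <- max(0, k - n2):min(k, m)
  lp <- lchoose(m, supp) + lchoose(n2, k - supp) - lchoose(N, k)
  p <- exp(lp)
  pobs <- exp(lchoose(m, tp) + lchoose(n2, k - tp) - lchoose(N, k))
  sum(p[p <= pobs * (1 + 1e-7)])
}

test_that("Fisher's exact test equals enumeration and the reference routine", {
  expect_equal(fisher_exact(contingency_table(1, 1, 1, 1)), 1.0)
  expect_lt(fisher_exact(contingency_table(4, 2, 4, 72)), 0.001)
  set.seed(9)
  for (rep in 1:200) {
    cts <- as.integer(rmultinom(1, sample(4:200, 1), runif(4, 0.05, 1)))
    tab <- contingency_table(cts[1], cts[2], cts[3], cts[4])
    if (tab$tp + tab$fn == 0 || tab$fp + tab$tn == 0) next
    p <- fisher_exact(tab)
    expect_equal(p, fisher_oracle(cts[1], cts[2], cts[3], cts[4]),
                 tolerance = 1e-10)
    pref <- stats::fisher.test(matrix(c(cts[1], cts[2], cts[3], cts[4]), 2,
                                      byrow = TRUE))$p.value
    expect_equal(p, min(pref, 1), tolerance = 1e-7)
  }
})

test_that("kappa: worked example, fixed points, table form equals formula form", {
  k <- cohen_kappa(0.60, 0.31)
  expect_equal(k$kappa, 0.42, tolerance = 0.005)
  expect_equal(cohen_kappa(0.5, 0.5)$kappa, 0)
  expect_equal(cohen_kappa(1, 0.31)$kappa, 1)
  expect_error(cohen_kappa(0.5, 1), "p_e")
  set.seed(12)
  for (rep in 1:10) {
    m <- matrix(rpois(16, 6), 4, 4)
    kt <- cohen_kappa_table(m)
    p_o <- sum(diag(m)) / sum(m)
    p_e <- sum(rowSums(m) * colSums(m)) / sum(m)^2
    expect_equal(kt$kappa, cohen_kappa(p_o, p_e)$kappa, tolerance = 1e-12)
  }
})

test_that("OLS matches the normal-equations oracle and exact fits", {
  set.seed(3)
  X <- cbind(rnorm(20), rnorm(20), rnorm(20))
  colnames(X) <- c("a", "b", "c")
  y <- 2 + X %*% c(1, -3, 0.5) + rnorm(20)
  fit <- ols_fit(X, y)
  Xi <- cbind(1, X)
  beta <- solve(t(Xi) %*% Xi, t(Xi) %*% y)
  expect_equal(unname(coef(fit)), as.vector(beta), tolerance = 1e-8)
  # classical SEs from the oracle
  res <- y - Xi %*% beta
  s2 <- sum(res^2) / (20 - 4)
  se <- sqrt(diag(s2 * solve(t(Xi) %*% Xi)))
  expect_equal(fit$coefficients$se, unname(se), tolerance = 1e-8)
  # exact linear data: R^2 = 1, residuals 0
  y0 <- 1 + X %*% c(2, 0, -1)
  fit0 <- suppressWarnings(ols_fit(X, y0))
  expect_equal(fit0$r2, 1)
  expect_lt(max(abs(stats::residuals(fit0$fit))), 1e-10)
  # adjusted R^2 identity
  n <- fit$n; p <- 3
  expect_equal(fit$adj_r2, 1 - (1 - fit$r2) * (n - 1) / (n - p - 1))
  expect_lte(fit$adj_r2, fit$r2)
  # rank deficiency is an error
  expect_error(ols_fit(cbind(X, a2 = X[, 1]), y), "rank")
})

test_that("logistic fit: calibration under a null effect, error cases", {
  set.seed(8)
  cover <- vapply(1:50, function(r) {
    x <- rnorm(5000)
    y <- rbinom(5000, 1, 0.3)       # no covariate effect
    fit <- logistic_fit(cbind(x = x), y)
    co <- fit$coefficients[fit$coefficients$term == "x", ]
    co$or_lower <= 1 && 1 <= co$or_upper
  }, logical(1))
  expect_gte(mean(cover), 0.9)
  expect_error(logistic_fit(cbind(x = rnorm(20)), rep(1, 20)), "outcome")
  # complete separation
  xs <- c(rep(-2, 20), rep(2, 20)) + runif(40, 0, 0.1)
  ys <- as.integer(xs > 0)
  expect_error(logistic_fit(cbind(x = xs), ys), "separation")
})

test_that("bootstrap intervals are deterministic and sanely calibrated", {
  set.seed(5)
  x <- rnorm(50)
  ci1 <- bootstrap_bca_ci(x, mean, B = 2000, seed = 17)
  ci2 <- bootstrap_bca_ci(x, mean, B = 2000, seed = 17)
  expect_identical(ci1, ci2)
  expect_lt(ci1[["lower"]], mean(x))
  expect_gt(ci1[["upper"]], mean(x))
  # degenerate statistic collapses to a point with a warning
  expect_warning(ci0 <- bootstrap_bca_ci(x, function(s) 1, B = 1000, seed = 1),
                 "degenerate")
  expect_equal(unname(ci0), c(1, 1), ignore_attr = TRUE)
  # BCa variant runs and stays ordered
  cib <- bootstrap_bca_ci(x, mean, B = 2000, seed = 17, method = "bca")
  expect_lt(cib[["lower"]], cib[["upper"]])
  expect_error(bootstrap_bca_ci(x[1:5], mean), "sample size")
  expect_error(bootstrap_bca_ci(x, mean, B = 100), "B must")
})

test_that("bootstrap coverage of the mean is near nominal", {
  hits <- vapply(1:200, function(r) {
    set.seed(1000 + r)
    x <- rnorm(50)
    ci <- bootstrap_bca_ci(x, mean, B = 1000, seed = r)
    ci[["lower"]] <= 0 && 0 <= ci[["upper"]]
  }, logical(1))
  expect_gte(mean(hits), 0.90)
  expect_lte(mean(hits), 0.99)
})

test_that("contingency tables can be tallied from logical vectors", {
  pred <- c(TRUE, TRUE, FALSE, FALSE, TRUE)
  out <- c(TRUE, FALSE, TRUE, FALSE, FALSE)
  tab <- contingency_table(predictor = pred, outcome = out)
  expect_identical(c(tab$tp, tab$fn, tab$fp, tab$tn), c(1L, 1L, 2L, 1L))
  expect_error(contingency_table(0, 0, 0, 0), "total")
})

test_that("cohort_report wires the pieces together on a simulated cohort", {
  co <- make_cohort(cohort_spec(n_subjects = 400, seed = 31))
  rep <- cohort_report(co)
  expect_s3_class(rep$ols_multivariable, "regression_result")
  expect_equal(sum(dichotomize_severe(co$ndwma)), 40)   # 10% above P90
  cm <- rep$ols_multivariable$coefficients
  est <- cm$estimate[cm$term == "dwma_per10pct"]
  expect_lt(est, 0)                 # direction of the generating model
  expect_true(all(vapply(rep$properties, function(p)
    p$sensitivity$estimate >= 0 && p$sensitivity$estimate <= 1, logical(1))))
})
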