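#' Specification of a simulated very-preterm cohort
#'
#' Defines the generating model for a simulated cohort of very preterm
#' infants scanned at term-equivalent age and followed to 3 years. The
#' Bayley-III Motor composite is generated as a linear function of
#' normalized DWMA volume (scaled so the coefficient is per 10-percentage-
#' point increase), gestational age, and the global brain abnormality
#' score, plus Gaussian residual noise; scores are floored at 40 and capped
#' at 160 as on the real scale (children untestable due to severe
#' disability are conventionally assigned the scale floor, 3 SD or more
#' below the normative mean of 100). Cerebral palsy is Bernoulli with a
#' logistic dependence on normalized DWMA.
#'
#' Normalized DWMA volume is drawn from a log-normal distribution
#' truncated at `cap`; its median (~0.007) and right skew emulate the
#' scale observed in very preterm cohorts, while the cap keeps volumes in
#' the physically plausible range (a quarter of the white matter). Defaults for the effect sizes are a motor coefficient
#' of -12.59 Bayley points and a CP log-odds of log(31.64), both per
#' 10-percentage-point increase in normalized DWMA; gestational age
#' contributes 1.28 points per week.
#'
#' @param n_subjects number of infants.
#' @param intercept intercept of the Bayley model (points).
#' @param beta_dwma_per10pct Bayley points per 10-percentage-point increase
#'   in normalized DWMA volume.
#' @param beta_ga Bayley points per week of gestational age.
#' @param beta_global Bayley points per point of global abnormality score.
#' @param residual_sd residual SD of the Bayley model (points).
#' @param cp_log_odds_per10pct CP log odds per 10-percentage-point increase
#'   in normalized DWMA.
#' @param cp_intercept CP model intercept (log odds at zero DWMA).
#' @param dwma_distribution list with `meanlog`, `sdlog`, `cap` of the
#'   truncated log-normal normalized-DWMA distribution.
#' @param seed integer RNG seed.
#' @return object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_subjects = 77,
                        intercept = 62.5,
                        beta_dwma_per10pct = -12.59,
                        beta_ga = 1.28,
                        beta_global = -0.89,
                        residual_sd = 9.4,
                        cp_log_odds_per10pct = log(31.64),
                        cp_intercept = -3.8,
                        dwma_distribution = list(meanlog = log(0.0073), sdlog = 1.9,
                                                 cap = 0.25),
                        seed = 1L) {
  n_subjects <- as.integer(n_subjects)
  if (n_subjects <= 0) stop("n_subjects must be > 0")
  if (residual_sd < 0) stop("residual_sd must be >= 0")
  if (is.null(dwma_distribution$meanlog) || is.null(dwma_distribution$sdlog))
    stop("dwma_distribution needs `meanlog` and `sdlog`")
  structure(list(n_subjects = n_subjects,
                 intercept = intercept,
                 beta_dwma_per10pct = beta_dwma_per10pct,
                 beta_ga = beta_ga,
                 beta_global = beta_global,
                 residual_sd = residual_sd,
                 cp_log_odds_per10pct = cp_log_odds_per10pct,
                 cp_intercept = cp_intercept,
                 dwma_distribution = dwma_distribution,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Simulate a cohort of very preterm infants
#'
#' Draws one subject record per infant under the generating model of
#' [cohort_spec()]. Gestational age is Normal(28.3, 2.4) truncated to
#' \[23, 32\] weeks; PMA at MRI is Normal(40.3, 0.5) weeks; sex and
#' centre are sampled with realistic frequencies; the Kidokoro global
#' abnormality score is Poisson(2.8); the visual DWMA grade (0-3) is
#' drawn from frequencies typical of term-equivalent reads and is, by
#' construction, unrelated to true DWMA volume (visual grading carries
#' no signal in this simulation).
#'
#' @param spec a [cohort_spec()].
#' @return a `data.frame` with one row per infant: `id`,
#'   `gestational_age` (weeks), `male` (0/1), `pma_at_mri` (weeks),
#'   `center` (factor, 4 levels), `global_score` (integer),
#'   `visual_dwma_grade` (0-3), `ndwma` (normalized DWMA volume,
#'   fraction in \[0,1)), `bayley_motor` (40-160), `cp` (0/1).
#' @export
make_cohort <- function(spec = cohort_spec()) {
  if (!inherits(spec, "cohort_spec")) stop("`spec` must be a cohort_spec")
  n <- spec$n_subjects
  with_seed(spec$seed, {
    ga <- pmin(pmax(stats::rnorm(n, 28.3, 2.4), 23), 32)
    male <- stats::rbinom(n, 1, 0.55)
    pma <- stats::rnorm(n, 40.3, 0.5)
    center <- factor(sample(paste0("C", 1:4), n, replace = TRUE,
                            prob = c(0.4, 0.25, 0.2, 0.15)))
    score <- stats::rpois(n, 2.8)
    grade <- sample(0:3, n, replace = TRUE, prob = c(0.35, 0.25, 0.27, 0.13))
    cap <- spec$dwma_distribution$cap %||% 0.25
    ndwma <- pmin(stats::rlnorm(n, spec$dwma_distribution$meanlog,
                                spec$dwma_distribution$sdlog), cap)
    x10 <- ndwma * 10       # units of 10 percentage points
    bayley <- spec$intercept +
      spec$beta_dwma_per10pct * x10 +
      spec$beta_ga * ga +
      spec$beta_global * score +
      stats::rnorm(n, 0, spec$residual_sd)
    bayley <- pmin(pmax(bayley, 40), 160)
    cp <- stats::rbinom(n, 1, stats::plogis(spec$cp_intercept +
                                              spec$cp_log_odds_per10pct * x10))
    data.frame(id = sprintf("VP%04d", seq_len(n)),
               gestational_age = ga,
               male = male,
               pma_at_mri = pma,
               center = center,
               global_score = score,
               visual_dwma_grade = grade,
               ndwma = ndwma,
               bayley_motor = bayley,
               cp = cp,
               stringsAsFactors = FALSE)
  })
}

#' Read / write a cohort table as CSV
#' @param cohort a cohort `data.frame` from [make_cohort()].
#' @param path CSV path.
#' @return `path` (write) or a `data.frame` (read).
#' @export
write_cohort <- function(cohort, path) {
  utils::write.csv(cohort, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  if ("center" %in% names(x)) x$center <- factor(x$center)
  x
}
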