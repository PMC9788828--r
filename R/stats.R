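# Nonparametric tests, effect sizes, a-priori power analysis, bootstrap
# feeder precision and feeding-log fidelity summaries.

#' Two-tailed Wilcoxon matched-pairs signed-rank test
#'
#' Zero differences are dropped. The exact null distribution is used when
#' at most 25 nonzero pairs remain and the absolute differences are free of
#' ties; otherwise a tie-corrected normal approximation (with continuity
#' correction) is used. The `exact` flag in the result records which path
#' was taken.
#'
#' @param x,y Paired numeric vectors of equal length.
#' @return A one-row tibble: `statistic`, `p_value`, `method`, `n`
#'   (nonzero pairs), `exact`.
#' @export
wilcoxon_signed_rank <- function(x, y) {
  stopifnot(length(x) == length(y))
  ok <- stats::complete.cases(x, y)
  d <- x[ok] - y[ok]
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L) {
    warn("All paired differences are zero; p = 1.")
    return(tibble(statistic = NA_real_, p_value = 1,
                  method = "wilcoxon_signed_rank", n = 0L, exact = TRUE))
  }
  ties <- anyDuplicated(abs(d)) > 0L
  exact <- n <= 25L && !ties
  ht <- suppressWarnings(
    stats::wilcox.test(d, exact = exact, correct = TRUE)
  )
  tibble(statistic = unname(ht$statistic), p_value = ht$p.value,
         method = "wilcoxon_signed_rank", n = n, exact = exact)
}

#' Two-sided Wilcoxon rank-sum (Mann-Whitney) test
#'
#' Exact when the pooled sample has at most 20 observations and no ties,
#' otherwise a tie-corrected normal approximation with continuity
#' correction.
#'
#' @param x,y Numeric vectors (the two groups).
#' @return A one-row tibble: `statistic` (Mann-Whitney U of `x`),
#'   `p_value`, `method`, `n1`, `n2`, `exact`.
#' @export
wilcoxon_rank_sum <- function(x, y) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (length(x) == 0L || length(y) == 0L) abort("Both groups must be non-empty.")
  ties <- anyDuplicated(c(x, y)) > 0L
  exact <- (length(x) + length(y)) <= 20L && !ties
  ht <- suppressWarnings(stats::wilcox.test(x, y, exact = exact,
                                            correct = TRUE))
  tibble(statistic = unname(ht$statistic), p_value = ht$p.value,
         method = "wilcoxon_rank_sum", n1 = length(x), n2 = length(y),
         exact = exact)
}

#' Pearson correlation coefficient
#'
#' @param x,y Numeric vectors; pairs with a missing value are dropped.
#' @return The sample correlation in `[-1, 1]`.
#' @export
pearson_r <- function(x, y) {
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L) abort("Need at least 3 complete pairs.")
  if (sd(x) == 0 || sd(y) == 0) abort("Zero variance; correlation undefined.")
  stats::cor(x, y)
}

#' Cohen's d with a confidence interval
#'
#' Standardised mean difference `(mean(x) - mean(y)) / s_pooled` with the
#' pooled (df-weighted) standard deviation, and the normal-theory interval
#' `d +/- t * sqrt((n1+n2)/(n1 n2) + d^2 / (2 (n1+n2)))`.
#'
#' @param x,y Numeric vectors with at least 2 values each.
#' @param conf Confidence level.
#' @return A one-row tibble: `d`, `ci_low`, `ci_high`, `n1`, `n2`, `conf`.
#' @export
cohens_d_ci <- function(x, y, conf = 0.95) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  n1 <- length(x); n2 <- length(y)
  stopifnot(n1 >= 2, n2 >= 2)
  sp2 <- ((n1 - 1) * stats::var(x) + (n2 - 1) * stats::var(y)) /
    (n1 + n2 - 2)
  if (sp2 == 0) abort("Zero pooled variance; d undefined.")
  d <- (mean(x) - mean(y)) / sqrt(sp2)
  ci <- cohens_d_interval(d, n1, n2, conf)
  tibble(d = d, ci_low = ci[1], ci_high = ci[2], n1 = n1, n2 = n2,
         conf = conf)
}

#' @rdname cohens_d_ci
#' @param d A Cohen's d value (used with group sizes only, when the raw
#'   data are unavailable).
#' @param n1,n2 Group sizes.
#' @return `cohens_d_interval()`: a length-2 vector `c(low, high)`.
#' @export
cohens_d_interval <- function(d, n1, n2, conf = 0.95) {
  se <- sqrt((n1 + n2) / (n1 * n2) + d^2 / (2 * (n1 + n2)))
  tq <- stats::qt((1 + conf) / 2, df = n1 + n2 - 2)
  c(d - tq * se, d + tq * se)
}

# Asymptotic relative efficiency of the WMW test vs the t test for the
# supported parent distributions (the "min ARE" entry is the distribution-
# free lower bound 0.864).
wmw_are <- function(parent) {
  switch(parent,
         normal = 3 / pi,
         min_are = 0.864,
         logistic = pi^2 / 9,
         laplace = 1.5,
         uniform = 1,
         abort(paste0("Unknown parent distribution '", parent, "'.")))
}

# Power of the two-sided two-sample t test at (possibly fractional)
# per-group sizes m1, m2 via the noncentral t distribution.
t_test_power <- function(d, m1, m2, alpha) {
  df <- m1 + m2 - 2
  ncp <- abs(d) * sqrt(m1 * m2 / (m1 + m2))
  crit <- stats::qt(1 - alpha / 2, df)
  1 - stats::pt(crit, df, ncp) + stats::pt(-crit, df, ncp)
}

#' A-priori sample size for the Wilcoxon-Mann-Whitney test (A.R.E. method)
#'
#' Finds the smallest per-group sample size whose *effective* sizes --
#' the nominal sizes deflated by the asymptotic relative efficiency of the
#' WMW test under the chosen parent distribution (`3/pi` for a normal
#' parent) -- give the two-sided two-sample t test at effect size `d` the
#' requested power. This is the classical A.R.E. approximation for rank
#' tests: the WMW test at n observations behaves like a t test at
#' `ARE * n` observations.
#'
#' @param d Effect size (Cohen's d); sign is ignored.
#' @param alpha Two-sided type-I error rate.
#' @param power Target power, must exceed `alpha`.
#' @param parent Parent distribution for the ARE: `"normal"` (3/pi),
#'   `"min_are"` (0.864), `"logistic"`, `"laplace"` or `"uniform"`.
#' @param ratio Allocation ratio n2/n1.
#' @return Named integer vector `c(n1, n2)`, animals per group.
#' @export
#' @examples
#' wmw_sample_size(0.7862264) # 28 per group
wmw_sample_size <- function(d, alpha = 0.05, power = 0.8,
                            parent = "normal", ratio = 1) {
  if (d == 0) abort("Effect size must be nonzero.")
  stopifnot(alpha > 0, alpha < 1, power > 0, power < 1, ratio > 0)
  if (power <= alpha) abort("Target power must exceed alpha.")
  are <- wmw_are(parent)
  n1 <- 2L
  repeat {
    n2 <- max(2L, as.integer(ceiling(ratio * n1)))
    if (t_test_power(d, are * n1, are * n2, alpha) >= power) break
    n1 <- n1 + 1L
    if (n1 > 1e6L) abort("Sample-size search did not terminate.")
  }
  c(n1 = n1, n2 = n2)
}

#' Bootstrap precision of feeding masses
#'
#' The dispersion of delivered food masses is summarised as the mean over
#' `B` ordinary nonparametric bootstrap resamples of the sample standard
#' deviation; precision is the reciprocal of its square (1/mg^2).
#'
#' @param masses Numeric vector of per-feeding masses (mg), n >= 2.
#' @param B Number of bootstrap replicates (>= 100).
#' @param seed Integer seed recorded in the result.
#' @return A one-row tibble: `n`, `sd_boot` (mg), `precision` (1/mg^2),
#'   `B`, `seed`.
#' @export
bootstrap_precision <- function(masses, B = 1000, seed = 1) {
  masses <- masses[!is.na(masses)]
  n <- length(masses)
  stopifnot(n >= 2, B >= 100)
  if (stats::sd(masses) == 0) {
    abort("Zero-variance sample: precision would be infinite.")
  }
  set.seed(seed)
  sds <- vapply(seq_len(B), function(i) {
    stats::sd(sample(masses, n, replace = TRUE))
  }, numeric(1))
  sd_boot <- mean(sds)
  tibble(n = n, sd_boot = sd_boot, precision = 1 / sd_boot^2, B = B,
         seed = seed)
}

#' Feeder fidelity summary from a scheduled/confirmed log
#'
#' Worked example of the feeding arithmetic these logs encode: an ad
#' libitum schedule delivers 7 x 5 mg = 35 mg/day, the restricted schedule
#' 3 x 5 mg = 15 mg/day, i.e. a `100 * (1 - 15/35)` = ~57\% restriction; a
#' feeder confirming 206 of 210 scheduled drops has 98.1\% fidelity.
#'
#' @param log Tibble with per-day `scheduled` and `confirmed` feeding
#'   counts (any other columns, e.g. feeder or day ids, are ignored).
#' @return A list of class `fidelity_summary`: total `scheduled` and
#'   `confirmed`, `pct_confirmed` (percent, half-up to 1 decimal;
#'   `pct_confirmed_raw` unrounded), and `histogram`, a tibble of per-day
#'   deviations (`deviation`, `n_days`, `pct_days`).
#' @export
fidelity_summary <- function(log) {
  stopifnot(all(c("scheduled", "confirmed") %in% names(log)))
  if (any(log$scheduled < 0 | log$confirmed < 0)) {
    abort("Negative feeding counts are invalid.")
  }
  if (any(log$confirmed > log$scheduled)) {
    abort("confirmed must be <= scheduled for every day.")
  }
  dev <- log$scheduled - log$confirmed
  hist <- tibble(deviation = dev) |>
    count(.data$deviation, name = "n_days") |>
    mutate(pct_days = 100 * .data$n_days / sum(.data$n_days))
  raw <- 100 * sum(log$confirmed) / sum(log$scheduled)
  structure(
    list(scheduled = sum(log$scheduled), confirmed = sum(log$confirmed),
         pct_confirmed = round_half_up(raw, 1), pct_confirmed_raw = raw,
         histogram = hist),
    class = "fidelity_summary"
  )
}

#' @export
print.fidelity_summary <- function(x, ...) {
  cat("<fidelity_summary> ", x$confirmed, "/", x$scheduled,
      " confirmed (", x$pct_confirmed, "%) over ",
      sum(x$histogram$n_days), " feeder-days\n", sep = "")
  print(x$histogram)
  invisible(x)
}
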