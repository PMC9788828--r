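# Kaplan-Meier medians, lifespan extension, log-rank tests, censored
# Gompertz maximum likelihood ("frailty" and "rate of aging") and binned
# empirical hazard. Lifespans are exact (deaths recorded on the day found);
# censored animals carry observed = 0.

check_surv <- function(data) {
  stopifnot(all(c("lifespan_days", "observed") %in% names(data)))
  if (any(data$lifespan_days <= 0)) abort("Lifespans must be positive.")
  if (any(!data$observed %in% c(0, 1))) abort("observed must be 0/1.")
  invisible(data)
}

#' Kaplan-Meier median lifespan
#'
#' The earliest time at which the Kaplan-Meier survival estimate drops to
#' 0.5 or below; `NA` when the curve never reaches 0.5.
#'
#' @param data Tibble with columns `lifespan_days` and `observed`
#'   (1 = death, 0 = censored).
#' @return Median lifespan in days, or `NA`.
#' @export
km_median <- function(data) {
  check_surv(data)
  if (sum(data$observed) == 0) abort("No observed events.")
  fit <- survival::survfit(
    survival::Surv(lifespan_days, observed) ~ 1, data = data
  )
  idx <- which(fit$surv <= 0.5)
  if (length(idx) == 0L) NA_real_ else fit$time[min(idx)]
}

#' Percent change in median lifespan
#'
#' @param median_ref Reference median (days), must be positive.
#' @param median_test Test-group median (days).
#' @return Percent extension, rounded half-up to 1 decimal.
#' @export
#' @examples
#' percent_extension(95, 116) # 22.1
percent_extension <- function(median_ref, median_test) {
  stopifnot(median_ref > 0)
  round_half_up(100 * (median_test - median_ref) / median_ref, 1)
}

#' Log-rank test between two groups
#'
#' @param data Survival tibble (see [km_median()]) plus a grouping column.
#' @param group Name of the grouping column (must have exactly two levels,
#'   each with at least one event).
#' @return A one-row tibble: `statistic` (chi-square, 1 df), `p_value`,
#'   `method`, `n1`, `n2`.
#' @export
logrank_test <- function(data, group = "diet") {
  check_surv(data)
  g <- factor(data[[group]])
  if (nlevels(g) != 2L) abort("Grouping column must have exactly 2 levels.")
  ev <- tapply(data$observed, g, sum)
  if (any(ev == 0)) abort("Each group needs at least one observed event.")
  sd1 <- survival::survdiff(
    survival::Surv(lifespan_days, observed) ~ g,
    data = mutate(data, g = g)
  )
  tibble(statistic = unname(sd1$chisq),
         p_value = stats::pchisq(sd1$chisq, df = 1, lower.tail = FALSE),
         method = "log-rank",
         n1 = sum(g == levels(g)[1]), n2 = sum(g == levels(g)[2]))
}

# Negative log-likelihood for censored Gompertz data in
# theta = (log a, b): hazard h(t) = a e^{bt}, cumulative hazard
# H(t) = a/b (e^{bt} - 1), with the exponential limit a t as b -> 0.
gompertz_negll <- function(theta, t, d) {
  a <- exp(theta[1]); b <- theta[2]
  H <- if (abs(b) < 1e-9) a * t else (a / b) * expm1(b * t)
  ll <- sum(d * (log(a) + b * t)) - sum(H)
  if (!is.finite(ll)) return(1e10)
  -ll
}

# Analytic gradient of gompertz_negll in (log a, b).
gompertz_negll_grad <- function(theta, t, d) {
  a <- exp(theta[1]); b <- theta[2]
  if (abs(b) < 1e-9) {
    H <- a * t
    dH_db <- a * t^2 / 2
  } else {
    H <- (a / b) * expm1(b * t)
    dH_db <- (a / b) * t * exp(b * t) - H / b
  }
  g_loga <- sum(d) - sum(H)
  g_b <- sum(d * t) - sum(dH_db)
  -c(g_loga, g_b)
}

#' Censored Gompertz maximum-likelihood fit
#'
#' Fits the Gompertz hazard `h(t) = a exp(b t)` to right-censored
#' lifespans by maximising the censored log-likelihood, with the rate `a`
#' log-parameterised for positivity and the optimisation initialised from
#' the exponential fit. The shape `b` is the "rate of aging" (slope of
#' ln hazard versus time) and the rate `a` the "frailty" (baseline
#' hazard).
#'
#' Because the parameters scale with the time unit (`a` and `b` are per
#' unit), the unit is an explicit argument; `time_unit = 27` (27-day bins)
#' reproduces the scale on which published killifish estimates are
#' reported, and the fit also reports day-scale parameters.
#'
#' @param data Survival tibble (`lifespan_days`, `observed`).
#' @param time_unit Days per time unit used for fitting.
#' @param conf Confidence level for the Wald intervals (rate interval on
#'   the log scale).
#' @return An object of class `gompertz_fit` with elements `rate`,
#'   `shape`, `ci_rate`, `ci_shape`, `rate_per_day`, `shape_per_day`,
#'   `loglik`, `n`, `n_events`, `time_unit`, `converged`, `vcov` and the
#'   data used. Has [tidy()], [glance()] and [autoplot()] methods.
#' @export
gompertz_fit <- function(data, time_unit = 1, conf = 0.95) {
  check_surv(data)
  if (sum(data$observed) < 5) abort("Need at least 5 observed events.")
  t <- data$lifespan_days / time_unit
  d <- data$observed
  a0 <- sum(d) / sum(t)
  init <- c(log(a0), 0.01)
  opt <- stats::optim(init, gompertz_negll, gr = gompertz_negll_grad,
                      t = t, d = d, method = "BFGS", hessian = TRUE,
                      control = list(maxit = 1000, reltol = 1e-14))
  if (opt$convergence != 0) {
    abort(paste0("Gompertz fit did not converge (code ", opt$convergence,
                 ")."))
  }
  vc <- tryCatch(solve(opt$hessian), error = function(e) {
    abort("Observed information is singular; no standard errors.")
  })
  z <- stats::qnorm((1 + conf) / 2)
  se <- sqrt(pmax(diag(vc), 0))
  a <- exp(opt$par[1]); b <- opt$par[2]
  structure(
    list(rate = a, shape = b,
         ci_rate = a * exp(c(-1, 1) * z * se[1]),
         ci_shape = b + c(-1, 1) * z * se[2],
         rate_per_day = a / time_unit, shape_per_day = b / time_unit,
         loglik = -opt$value, n = nrow(data), n_events = sum(d),
         time_unit = time_unit, conf = conf, converged = TRUE,
         vcov = vc, data = data),
    class = "gompertz_fit"
  )
}

#' @export
print.gompertz_fit <- function(x, ...) {
  cat("<gompertz_fit> h(t) = a exp(b t), time unit =", x$time_unit,
      "day(s)\n")
  cat(sprintf("  rate a (frailty):      %.4f  [%.4f, %.4f]\n",
              x$rate, x$ci_rate[1], x$ci_rate[2]))
  cat(sprintf("  shape b (rate of aging): %.4f  [%.4f, %.4f]\n",
              x$shape, x$ci_shape[1], x$ci_shape[2]))
  cat(sprintf("  loglik %.2f on %d animals (%d deaths)\n", x$loglik, x$n,
              x$n_events))
  invisible(x)
}

#' @export
tidy.gompertz_fit <- function(x, ...) {
  tibble(
    term = c("rate", "shape"),
    estimate = c(x$rate, x$shape),
    ci_low = c(x$ci_rate[1], x$ci_shape[1]),
    ci_high = c(x$ci_rate[2], x$ci_shape[2]),
    per_day = c(x$rate_per_day, x$shape_per_day)
  )
}

#' @export
glance.gompertz_fit <- function(x, ...) {
  tibble(loglik = x$loglik, n = x$n, n_events = x$n_events,
         time_unit = x$time_unit, converged = x$converged)
}

#' Binned empirical hazard
#'
#' Discrete life-table hazard: for bins `[0, w), [w, 2w), ...` the hazard
#' is deaths in the bin divided by the number at risk at the bin start;
#' censored animals stay at risk through the bin containing their
#' censoring time.
#'
#' @param data Survival tibble.
#' @param bin_width Bin width in days (e.g. 21 for 3-week or 27-day bins).
#' @return A tibble of class `hazard_curve`: `bin_start`, `bin_mid`,
#'   `at_risk`, `deaths`, `hazard`, `ln_hazard` (NA where hazard is 0).
#' @export
binned_hazard <- function(data, bin_width) {
  check_surv(data)
  stopifnot(bin_width > 0)
  tmax <- max(data$lifespan_days)
  starts <- seq(0, tmax, by = bin_width)
  out <- purrr::map(starts, function(s) {
    at_risk <- sum(data$lifespan_days >= s)
    deaths <- sum(data$observed == 1 & data$lifespan_days >= s &
                    data$lifespan_days < s + bin_width)
    tibble(bin_start = s, bin_mid = s + bin_width / 2,
           at_risk = at_risk, deaths = deaths,
           hazard = if (at_risk > 0) deaths / at_risk else NA_real_)
  }) |> list_rbind() |>
    mutate(ln_hazard = ifelse(!is.na(.data$hazard) & .data$hazard > 0,
                              log(.data$hazard), NA_real_))
  attr(out, "bin_width") <- bin_width
  class(out) <- c("hazard_curve", class(out))
  out
}
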