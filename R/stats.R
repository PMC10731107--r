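#' Percent change and monthly rate
#'
#' `percent_change(pre, post)` is `(post - pre) / pre * 100`;
#' `monthly_rate(pct, months)` divides a percent change by the elapsed time in
#' months. Both are vectorised.
#'
#' @param pre_value,post_value numeric; `pre_value` must be non-zero.
#' @return Percent change (%), or rate (%/month).
#' @export
percent_change <- function(pre_value, post_value) {
  if (any(pre_value == 0, na.rm = TRUE)) {
    stop("percent_change: preflight value is zero", call. = FALSE)
  }
  (post_value - pre_value) / pre_value * 100
}

#' @rdname percent_change
#' @param pct percent change (%).
#' @param months elapsed duration in months (> 0).
#' @export
monthly_rate <- function(pct, months) {
  if (any(!is.finite(months) | months <= 0)) {
    stop("monthly_rate: months must be positive", call. = FALSE)
  }
  pct / months
}

stat_result <- function(estimate, s, n, t_statistic, df, p, comparison) {
  structure(list(estimate = estimate, sd = s, n = n, t_statistic = t_statistic,
                 df = df, p_two_sided = p, comparison = comparison),
            class = "stat_result")
}

#' @export
print.stat_result <- function(x, ...) {
  cat(sprintf("<stat_result> %s: %.4g +/- %.4g (n=%d), t(%d)=%.3f, p=%.4g\n",
              x$comparison, x$estimate, x$sd, x$n, x$df, x$t_statistic,
              x$p_two_sided))
  invisible(x)
}

#' One-sample t-test against zero
#'
#' Used for monthly rates of change: tests whether the per-subject
#' rates differ from 0. Two-sided, `df = n - 1`.
#'
#' @param values numeric vector (NA dropped), `n >= 2` with non-zero variance.
#' @param mu null value, default 0.
#' @param comparison label carried into the result.
#' @return A `stat_result`: `estimate` (mean), `sd`, `n`, `t_statistic`, `df`,
#'   `p_two_sided`.
#' @export
one_sample_ttest <- function(values, mu = 0, comparison = "vs 0") {
  values <- values[!is.na(values)]
  if (length(values) < 2L) {
    stop("one_sample_ttest: need at least 2 values", call. = FALSE)
  }
  if (sd(values) == 0) {
    stop("one_sample_ttest: zero variance", call. = FALSE)
  }
  tt <- t.test(values, mu = mu, alternative = "two.sided")
  stat_result(mean(values), sd(values), length(values),
              unname(tt$statistic), unname(tt$parameter), tt$p.value,
              comparison)
}

#' Paired t-test between two time points
#'
#' Subjects missing either value are dropped pairwise, so `n` reflects
#' complete pairs only (e.g. 15 of 17 at follow-up). The estimate is the mean
#' within-subject difference `post - pre`.
#'
#' @param pre_values,post_values numeric vectors aligned by subject.
#' @param comparison label carried into the result.
#' @return A `stat_result` on the within-subject differences.
#' @export
paired_ttest <- function(pre_values, post_values, comparison = "post vs pre") {
  if (length(pre_values) != length(post_values)) {
    stop("paired_ttest: vectors must be aligned by subject", call. = FALSE)
  }
  keep <- !is.na(pre_values) & !is.na(post_values)
  d <- post_values[keep] - pre_values[keep]
  if (length(d) < 2L) {
    stop("paired_ttest: fewer than 2 complete pairs", call. = FALSE)
  }
  if (sd(d) == 0) {
    stop("paired_ttest: zero variance of within-subject differences", call. = FALSE)
  }
  tt <- t.test(d, mu = 0, alternative = "two.sided")
  stat_result(mean(d), sd(d), length(d), unname(tt$statistic),
              unname(tt$parameter), tt$p.value, comparison)
}

#' Simple linear regression between two cohort metrics
#'
#' Ordinary least squares of `y` on `x` with the coefficient of determination
#' and the two-sided p-value of the slope; the bone metric is conventionally
#' the response and the muscle metric the predictor.
#'
#' @param x predictor values.
#' @param y response values.
#' @return List: `slope`, `intercept`, `r_squared`, `p`, `n`.
#' @export
linear_regression <- function(x, y) {
  keep <- !is.na(x) & !is.na(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3L) {
    stop("linear_regression: need at least 3 complete observations", call. = FALSE)
  }
  if (sd(x) == 0) {
    stop("linear_regression: predictor has zero variance", call. = FALSE)
  }
  if (sd(y) == 0) {
    # a constant response carries no explained variance
    return(list(slope = 0, intercept = y[1], r_squared = 0, p = 1,
                n = length(x)))
  }
  fit <- lm(y ~ x)
  sm <- summary(fit)
  list(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
       r_squared = sm$r.squared, p = sm$coefficients[2, 4], n = length(x))
}

#' Deterministic sample matching a printed mean and SD
#'
#' Builds an exactly mean/SD-matched sample from standardized normal
#' quantiles. Any sample with a given (mean, sd, n) yields the same one-sample
#' t statistic, so this reproduces t-tests reported only as summary
#' statistics.
#'
#' @param n sample size (>= 2).
#' @param mean,sd target sample mean and standard deviation.
#' @return Numeric vector of length `n` with exactly the requested mean and sd.
#' @export
summary_sample <- function(n, mean, sd) {
  if (n < 2L) stop("summary_sample: n must be >= 2", call. = FALSE)
  z <- qnorm((seq_len(n) - 0.5) / n)
  z <- (z - base::mean(z)) / stats::sd(z)
  mean + sd * z
}

#' Scale random draws to an exact sample mean and SD
#'
#' Normal draws standardized to hit the target moments exactly (the
#' `empirical` option of multivariate-normal samplers); used by the cohort
#' generator when `empirical_draws = TRUE` to remove finite-sample wobble from
#' injected effect distributions.
#'
#' @param n number of draws.
#' @param mean,sd target sample moments.
#' @param empirical if `FALSE`, plain i.i.d. `rnorm` draws.
#' @return Numeric vector of length `n`.
#' @export
rnorm_cohort <- function(n, mean, sd, empirical = FALSE) {
  if (n == 1L || !empirical || sd == 0) {
    return(rnorm(n, mean, sd))
  }
  z <- rnorm(n)
  z <- (z - base::mean(z)) / stats::sd(z)
  mean + sd * z
}
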