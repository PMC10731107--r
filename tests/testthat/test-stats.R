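test_that("percent change and monthly rate are exact arithmetic with guards", {
  expect_equal(percent_change(200, 190), -5)
  expect_equal(percent_change(123.4, 123.4), 0)
  expect_equal(percent_change(182.3, 173.97), -4.569391, tolerance = 1e-6)
  expect_error(percent_change(0, 10), "zero")
  expect_equal(monthly_rate(-5, 5), -1)
  expect_equal(monthly_rate(-6.48, 6), -1.08)
  expect_equal(monthly_rate(0, 7), 0)
  expect_error(monthly_rate(5, 0), "positive")
  expect_error(monthly_rate(5, -3), "positive")
})

test_that("one-sample t-test matches the closed form to 1e-9", {
  set.seed(2)
  x <- rnorm(12, 0.5, 1)
  res <- one_sample_ttest(x)
  tt <- mean(x) / (sd(x) / sqrt(length(x)))
  expect_equal(res$t_statistic, tt, tolerance = 1e-9)
  expect_equal(res$df, 11)
  expect_equal(res$p_two_sided, 2 * pt(-abs(tt), 11), tolerance = 1e-9)
  expect_equal(res$n, 12L)
  expect_error(one_sample_ttest(rep(1, 5)), "variance")
  expect_error(one_sample_ttest(3), "at least 2")
})

test_that("printed monthly-rate p-values are reproduced from summary triples", {
  # summary-equivalent samples built from (mean, sd, n); printed inputs are
  # rounded to two decimals, so agreement is to ~2 units in the last printed
  # digit of the p-value
  p_sup <- one_sample_ttest(summary_sample(17, -1.08, 1.13))$p_two_sided
  expect_lt(abs(p_sup - 0.0012), 2e-4)
  p_tra <- one_sample_ttest(summary_sample(17, -0.72, 0.77))$p_two_sided
  expect_lt(abs(p_tra - 0.0015), 2e-4)
  p_re <- one_sample_ttest(summary_sample(15, 0.39, 0.80))$p_two_sided
  expect_lt(abs(p_re - 0.079), 2e-3)
  # the constructed samples carry the moments exactly
  s <- summary_sample(17, -1.08, 1.13)
  expect_equal(mean(s), -1.08, tolerance = 1e-12)
  expect_equal(sd(s), 1.13, tolerance = 1e-12)
})

test_that("paired t-test drops incomplete pairs and matches the closed form", {
  set.seed(4)
  pre <- rnorm(10, 180, 20)
  post <- pre - rnorm(10, 8, 4)
  res <- paired_ttest(pre, post)
  d <- post - pre
  expect_equal(res$t_statistic, mean(d) / (sd(d) / sqrt(10)), tolerance = 1e-9)
  expect_equal(res$df, 9)

  # identical pairs have no signal but also no variance -> error, while a
  # constant shift with jitter is handled
  expect_error(paired_ttest(pre, pre + 5), "variance")
  post2 <- post
  post2[c(3, 7)] <- NA
  res2 <- paired_ttest(pre, post2)
  expect_equal(res2$n, 8L)
  expect_equal(res2$df, 7)
  expect_error(paired_ttest(pre[1], post[1]), "pairs")
})

test_that("regression matches hand-computed least squares to 1e-9", {
  x <- c(1, 2, 3, 4, 6)
  y <- c(2.3, 4.1, 5.8, 8.4, 11.9)
  r <- linear_regression(x, y)
  # closed forms, independent of lm
  bx <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  b0 <- mean(y) - bx * mean(x)
  yhat <- b0 + bx * x
  r2 <- 1 - sum((y - yhat)^2) / sum((y - mean(y))^2)
  se <- sqrt(sum((y - yhat)^2) / (length(x) - 2) / sum((x - mean(x))^2))
  p <- 2 * pt(-abs(bx / se), length(x) - 2)
  expect_equal(r$slope, bx, tolerance = 1e-9)
  expect_equal(r$intercept, b0, tolerance = 1e-9)
  expect_equal(r$r_squared, r2, tolerance = 1e-9)
  expect_equal(r$p, p, tolerance = 1e-9)

  # perfectly collinear points
  expect_equal(linear_regression(1:5, 2 * (1:5) + 1)$r_squared, 1,
               tolerance = 1e-12)
  # constant response carries no explained variance
  expect_equal(linear_regression(1:5, rep(3, 5))$r_squared, 0)
  expect_error(linear_regression(rep(1, 5), rnorm(5)), "variance")
  expect_error(linear_regression(1:2, 1:2), "at least 3")
})

test_that("cohort draws can match target moments exactly", {
  set.seed(8)
  x <- rnorm_cohort(17, -1.08, 1.13, empirical = TRUE)
  expect_equal(mean(x), -1.08, tolerance = 1e-12)
  expect_equal(sd(x), 1.13, tolerance = 1e-12)
  y <- rnorm_cohort(17, -1.08, 1.13, empirical = FALSE)
  expect_false(isTRUE(all.equal(mean(y), -1.08, tolerance = 1e-6)))
})
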