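test_that("ols_fit reproduces the construct-series R-squared and exact fits", {
  x <- c(30, 54, 64, 65, 69, 82)
  y <- c(7.8, 28.5, 34.7, 34.9, 35.4, 58.2)
  fit <- ols_fit(x, y)
  expect_equal(round(fit$R2, 2), 0.94)
  expect_equal(fit$r, pearson_r(x, y))

  exact <- ols_fit(1:10, 3 * (1:10) - 2)
  expect_equal(exact$R2, 1)
  expect_equal(exact$residuals, rep(0, 10))
  expect_equal(exact$A, 3)
  expect_equal(exact$b, -2)

  expect_error(ols_fit(rep(5, 10), rnorm(10)), "constant")
  expect_error(ols_fit(1:2, 1:2), "at least 3")
})

test_that("ols_fit equals lm and the closed-form normal equations", {
  set.seed(111)
  for (i in 1:50) {
    n <- sample(5:40, 1)
    x <- rnorm(n, 50, 8)
    y <- -1.5 * x + 100 + rnorm(n, 0, 6)
    fit <- ols_fit(x, y)
    ref <- stats::lm(y ~ x)
    expect_equal(fit$A, unname(coef(ref)[2]), tolerance = 1e-10)
    expect_equal(fit$b, unname(coef(ref)[1]), tolerance = 1e-10)
    expect_equal(fit$R2, summary(ref)$r.squared, tolerance = 1e-10)
    expect_equal(fit$adjR2, summary(ref)$adj.r.squared, tolerance = 1e-10)
    expect_equal(fit$s, summary(ref)$sigma, tolerance = 1e-10)
    expect_equal(sum(fit$residuals), 0, tolerance = 1e-8)
  }
})

test_that("prediction interval has the closed form at x_bar and widens away", {
  set.seed(222)
  x <- rnorm(20, 50, 5); y <- 2 * x + rnorm(20)
  fit <- ols_fit(x, y)
  at_mean <- prediction_interval(fit, fit$x_bar)
  tcrit <- qt(0.975, fit$df)
  expect_equal((at_mean$upper - at_mean$lower) / 2,
               tcrit * fit$s * sqrt(1 + 1 / fit$n), tolerance = 1e-12)

  xs <- fit$x_bar + c(0, 1, 3, 8, 20)
  widths <- with(prediction_interval(fit, xs), upper - lower)
  expect_true(all(diff(widths) > 0))

  # matches predict.lm's non-simultaneous prediction interval
  ref <- stats::lm(y ~ x)
  got <- prediction_interval(fit, c(40, 55, 62))
  exp <- predict(ref, newdata = data.frame(x = c(40, 55, 62)),
                 interval = "prediction", level = 0.95)
  expect_equal(got$lower, unname(exp[, "lwr"]), tolerance = 1e-10)
  expect_equal(got$upper, unname(exp[, "upr"]), tolerance = 1e-10)
})

test_that("prediction band achieves nominal coverage for new observations", {
  set.seed(333)
  n <- 20; covered <- logical(10000)
  for (i in seq_len(10000)) {
    x <- runif(n, 40, 80)
    y <- -1.764 * x + 124.817 + rnorm(n, 0, 7)
    fit <- ols_fit(x, y)
    x_new <- runif(1, 40, 80)
    y_new <- -1.764 * x_new + 124.817 + rnorm(1, 0, 7)
    band <- prediction_interval(fit, x_new)
    covered[i] <- y_new >= band$lower && y_new <= band$upper
  }
  expect_gte(mean(covered), 0.93)
  expect_lte(mean(covered), 0.97)
})

test_that("exp_fit recovers exact and noisy exponential parameters", {
  x <- seq(1, 40, by = 2)
  f <- exp_fit(x, 2 * exp(-0.05 * x))
  expect_equal(f$a, 2, tolerance = 1e-6)
  expect_equal(f$c, -0.05, tolerance = 1e-6)
  expect_equal(f$adjR2, 1, tolerance = 1e-9)

  # noisy data: agree with nls (port algorithm) as independent oracle
  set.seed(444)
  y <- 120 * exp(-0.03 * x) * exp(rnorm(length(x), 0, 0.02))
  f2 <- exp_fit(x, y)
  ref <- stats::nls(y ~ a * exp(c * x), start = list(a = 100, c = -0.02),
                    algorithm = "port")
  expect_equal(f2$a, unname(coef(ref)["a"]), tolerance = 1e-5)
  expect_equal(f2$c, unname(coef(ref)["c"]), tolerance = 1e-5)

  # linear data: both model fits are computable and finite
  ylin <- 100 - 1.5 * x + rnorm(length(x), 0, 2)
  f3 <- exp_fit(x, pmax(ylin, 1))
  expect_true(is.finite(f3$adjR2))
  expect_error(exp_fit(x, c(-1, rep(1, length(x) - 1))), "positive")
})

test_that("pearson_r matches the direct formula and handles edge inputs", {
  expect_equal(pearson_r(1:10, -(1:10)), -1)
  expect_equal(round(pearson_r(c(30, 54, 64, 65, 69, 82),
                               c(7.8, 28.5, 34.7, 34.9, 35.4, 58.2)), 2),
               0.97)
  set.seed(555)
  for (i in 1:30) {
    x <- rnorm(12); y <- rnorm(12)
    expect_equal(pearson_r(x, y), cor(x, y), tolerance = 1e-12)
  }
  expect_error(pearson_r(rep(1, 5), 1:5), "constant")
})

test_that("levene_test matches the mean-centred ANOVA form", {
  g <- rnorm(20)
  same <- levene_test(g, g)
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)

  set.seed(666)
  g1 <- rnorm(50); g2 <- 10 * rnorm(50)
  expect_lt(levene_test(g1, g2)$p_value, 1e-6)

  # against car::leveneTest with mean centring
  for (i in 1:20) {
    a <- rnorm(sample(5:30, 1)); b <- rnorm(sample(5:30, 1), sd = runif(1, 0.5, 3))
    ours <- levene_test(a, b)
    ref <- car::leveneTest(c(a, b), factor(rep(1:2, c(length(a), length(b)))),
                           center = mean)
    expect_equal(ours$statistic, ref[1, "F value"], tolerance = 1e-10)
    expect_equal(ours$p_value, ref[1, "Pr(>F)"], tolerance = 1e-10)
  }

  expect_warning(out <- levene_test(rep(1, 5), rep(2, 5)), "degenerate")
  expect_equal(out$p_value, 1)
})

test_that("welch one-tailed t matches t.test and is directionally correct", {
  g <- rnorm(20)
  expect_equal(welch_t_one_tailed(g, g)$p_value, 0.5)

  set.seed(777)
  g1 <- rnorm(30, 5, 1); g2 <- rnorm(30, 0, 1)
  expect_lt(welch_t_one_tailed(g1, g2)$p_value, 1e-10)
  expect_gt(welch_t_one_tailed(g2, g1)$p_value, 0.999)

  for (i in 1:20) {
    a <- rnorm(sample(5:30, 1)); b <- rnorm(sample(5:30, 1), sd = runif(1, 0.5, 3))
    ours <- welch_t_one_tailed(a, b)
    ref <- stats::t.test(a, b, alternative = "greater", var.equal = FALSE)
    expect_equal(ours$p_value, ref$p.value, tolerance = 1e-12)
    expect_equal(ours$df, unname(ref$parameter), tolerance = 1e-10)
  }
})

test_that("residual-model comparison behaves under null and inflation", {
  set.seed(888)
  x <- rnorm(30, 50, 6); y <- -x + rnorm(30, 0, 4)
  f1 <- ols_fit(x, y)
  expect_equal(compare_residual_models(f1, f1)$welch_one_tailed_P, 0.5)

  # inflate the "sizing" residuals threefold
  f_bad <- f1; f_bad$residuals <- 3 * f1$residuals
  cmp <- compare_residual_models(f_bad, f1)
  expect_lt(cmp$welch_one_tailed_P, 0.01)
  expect_gt(cmp$mean_abs_residuals[["sizing"]],
            cmp$mean_abs_residuals[["sequencing"]])
})

test_that("one-sided Fisher test reproduces known exact values", {
  expect_equal(round(fisher_exact_one_sided(4, 31, 1, 16), 3), 0.467)
  expect_equal(fisher_exact_one_sided(0, 10, 0, 10), 1)
  expect_equal(fisher_exact_one_sided(5, 0, 0, 5), 1 / choose(10, 5))
  expect_error(fisher_exact_one_sided(-1, 2, 3, 4), "non-negative")
})

test_that("one-sided Fisher matches fisher.test and direct enumeration", {
  set.seed(999)
  for (i in 1:60) {
    tab <- sample(0:15, 4, replace = TRUE)
    if (sum(tab[1:2]) == 0 || sum(tab[c(1, 3)]) == 0) next
    p <- fisher_exact_one_sided(tab[1], tab[2], tab[3], tab[4])
    ref <- stats::fisher.test(matrix(tab, 2, byrow = TRUE),
                              alternative = "greater")$p.value
    expect_equal(p, ref, tolerance = 1e-9)
    # direct enumeration with choose()
    r1 <- tab[1] + tab[2]; c1 <- tab[1] + tab[3]; N <- sum(tab)
    xs <- max(0, c1 - (N - r1)):min(r1, c1)
    probs <- choose(r1, xs) * choose(N - r1, c1 - xs) / choose(N, c1)
    expect_equal(p, sum(probs[xs >= tab[1]]), tolerance = 1e-12)
  }
})

test_that("slope estimates fall inside their own confidence interval at the
           nominal rate under the onset model", {
  set.seed(1234)
  hits <- logical(1000)
  for (i in seq_len(1000)) {
    x <- pmin(pmax(round(rnorm(31, 47, 5)), 39), 83)
    y <- -1.764 * x + 124.817 + rnorm(31, 0, 7)
    fit <- ols_fit(x, y)
    se_A <- fit$s / sqrt(fit$Sxx)
    ci <- fit$A + c(-1, 1) * qt(0.975, fit$df) * se_A
    hits[i] <- ci[1] <= -1.764 && -1.764 <= ci[2]
  }
  expect_gte(mean(hits), 0.93)
})
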