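# The statistical routines here are implemented from first principles so
# their behaviour (tail conventions, centring, adjusted-R2 degrees of
# freedom) is fully pinned down rather than inherited from a modelling
# front-end. Distribution functions (pt, pf, qt) are the standard base R
# ones.

#' Simple ordinary least squares fit
#'
#' Fits `y = A*x + b` by least squares in closed form and returns the
#' quantities needed downstream: coefficients, Pearson r, R-squared and
#' adjusted R-squared (one predictor), residuals, the residual standard
#' deviation `s` with `RSS/(n-2)`, and the predictor summaries (`x_bar`,
#' `Sxx`) that non-simultaneous prediction bounds require.
#'
#' @param x Numeric predictor vector (not constant, `n >= 3`).
#' @param y Numeric response vector, same length.
#' @return An object of class `linear_fit` with fields `A`, `b`, `r`,
#'   `R2`, `adjR2`, `n`, `residuals`, `fitted`, `s`, `x_bar`, `Sxx`,
#'   `df`, and the input `x`, `y`.
#' @examples
#' fit <- ols_fit(c(30, 54, 64, 65, 69, 82),
#'                c(7.8, 28.5, 34.7, 34.9, 35.4, 58.2))
#' round(fit$R2, 2) # 0.94
#' @export
ols_fit <- function(x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y)) stop("x and y must have equal length")
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L) stop("need at least 3 complete observations")
  x_bar <- mean(x); y_bar <- mean(y)
  Sxx <- sum((x - x_bar)^2)
  Syy <- sum((y - y_bar)^2)
  if (Sxx == 0) stop("degenerate fit: predictor is constant")
  Sxy <- sum((x - x_bar) * (y - y_bar))
  A <- Sxy / Sxx
  b <- y_bar - A * x_bar
  fitted <- A * x + b
  residuals <- y - fitted
  RSS <- sum(residuals^2)
  R2 <- if (Syy == 0) 1 else 1 - RSS / Syy
  r <- if (Syy == 0) NA_real_ else Sxy / sqrt(Sxx * Syy)
  df <- n - 2L
  structure(
    list(A = A, b = b, r = r, R2 = R2,
         adjR2 = 1 - (1 - R2) * (n - 1) / df,
         n = n, residuals = residuals, fitted = fitted,
         s = sqrt(RSS / df), x_bar = x_bar, Sxx = Sxx, df = df,
         x = x, y = y),
    class = "linear_fit"
  )
}

#' @export
print.linear_fit <- function(x, ...) {
  cat(sprintf("<linear_fit> y = %.4f * x + %.4f  (n = %d)\n", x$A, x$b, x$n))
  cat(sprintf("  r = %.4f, R2 = %.4f, adjR2 = %.4f, s = %.4f\n",
              x$r, x$R2, x$adjR2, x$s))
  invisible(x)
}

#' Predicted response of a linear fit
#'
#' @param fit A [ols_fit()] result.
#' @param x0 Predictor value(s).
#' @return Numeric vector of fitted responses.
#' @export
predict_fit <- function(fit, x0) fit$A * x0 + fit$b

#' Non-simultaneous prediction interval for a new observation
#'
#' The band expected to contain a single new observation at the stated
#' level (wider than the confidence band for the mean):
#' `yhat(x0) +/- t * s * sqrt(1 + 1/n + (x0 - x_bar)^2 / Sxx)` with the
#' t quantile on `n - 2` degrees of freedom.
#'
#' @param fit A [ols_fit()] result.
#' @param x0 Predictor value(s) at which to evaluate the band.
#' @param level Coverage level (default 0.95).
#' @return Data frame with columns `x0`, `fit`, `lower`, `upper`.
#' @export
prediction_interval <- function(fit, x0, level = 0.95) {
  tcrit <- stats::qt(1 - (1 - level) / 2, df = fit$df)
  half <- tcrit * fit$s * sqrt(1 + 1 / fit$n + (x0 - fit$x_bar)^2 / fit$Sxx)
  yhat <- predict_fit(fit, x0)
  data.frame(x0 = x0, fit = yhat, lower = yhat - half, upper = yhat + half)
}

#' Two-parameter exponential fit
#'
#' Fits `y = a * exp(c * x)` by damped Gauss-Newton least squares,
#' initialised from the log-linear fit of `log(y)` on `x`. The adjusted
#' R-squared is computed with one predictor, mirroring the linear model
#' it is compared against.
#'
#' @param x Numeric predictor vector.
#' @param y Numeric response vector, strictly positive, `n >= 3`.
#' @param max_iter Iteration cap (default 100).
#' @param tol Relative RSS convergence tolerance (default 1e-12).
#' @return An object of class `exp_fit` with fields `a`, `c`, `R2`,
#'   `adjR2`, `RSS`, `n`, `iterations`, `converged`, `residuals`.
#' @examples
#' f <- exp_fit(1:10, 2 * exp(-0.05 * (1:10)))
#' c(f$a, f$c) # 2, -0.05
#' @export
exp_fit <- function(x, y, max_iter = 100L, tol = 1e-12) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3L) stop("need at least 3 observations")
  if (any(y <= 0)) stop("exponential fit requires strictly positive y")
  # log-linear initialisation
  init <- ols_fit(x, log(y))
  theta <- c(a = exp(init$b), c = init$A)
  rss_of <- function(th) sum((y - th[1L] * exp(th[2L] * x))^2)
  rss <- rss_of(theta)
  trace <- rss
  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    ex <- exp(theta[2L] * x)
    res <- y - theta[1L] * ex
    J <- cbind(ex, theta[1L] * x * ex)
    step <- tryCatch(qr.solve(crossprod(J), crossprod(J, res)),
                     error = function(e) NULL)
    if (is.null(step) || any(!is.finite(step))) {
      converged <- TRUE  # stationary: Jacobian numerically singular
      break
    }
    lambda <- 1
    repeat {
      cand <- theta + lambda * as.numeric(step)
      rss_new <- rss_of(cand)
      if (is.finite(rss_new) && rss_new <= rss) break
      lambda <- lambda / 2
      if (lambda < 1e-12) break
    }
    if (lambda < 1e-12) {
      converged <- TRUE  # no descent direction improves: at the optimum
      break
    }
    theta <- theta + lambda * as.numeric(step)
    trace <- c(trace, rss_new)
    if (abs(rss - rss_new) <= tol * (rss + tol)) {
      rss <- rss_new
      converged <- TRUE
      break
    }
    rss <- rss_new
  }
  if (!converged && iter >= max_iter) {
    stop(structure(
      class = c("exp_fit_nonconvergence", "error", "condition"),
      list(message = paste0("exponential fit failed to converge after ",
                            iter, " iterations (RSS trace: ",
                            paste(signif(utils::tail(trace, 5L), 6),
                                  collapse = ", "), ")"),
           call = sys.call(-1L), trace = trace)))
  }
  n <- length(x)
  residuals <- y - theta[1L] * exp(theta[2L] * x)
  Syy <- sum((y - mean(y))^2)
  R2 <- if (Syy == 0) 1 else 1 - rss / Syy
  structure(
    list(a = unname(theta[1L]), c = unname(theta[2L]),
         R2 = R2, adjR2 = 1 - (1 - R2) * (n - 1) / (n - 2),
         RSS = rss, n = n, iterations = iter, converged = converged,
         residuals = residuals),
    class = "exp_fit"
  )
}

#' @export
print.exp_fit <- function(x, ...) {
  cat(sprintf("<exp_fit> y = %.4f * exp(%.4f * x)  (n = %d, adjR2 = %.4f)\n",
              x$a, x$c, x$n, x$adjR2))
  invisible(x)
}

#' Pearson product-moment correlation
#'
#' @param x,y Numeric vectors, `n >= 3`, neither constant.
#' @return The correlation coefficient.
#' @export
pearson_r <- function(x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y)) stop("x and y must have equal length")
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L) stop("need at least 3 complete observations")
  dx <- x - mean(x); dy <- y - mean(y)
  Sxx <- sum(dx^2); Syy <- sum(dy^2)
  if (Sxx == 0 || Syy == 0) stop("correlation undefined for constant input")
  sum(dx * dy) / sqrt(Sxx * Syy)
}

#' Levene's test for equality of variances (two groups)
#'
#' The classic mean-centred variant: an ANOVA F statistic on the
#' absolute deviations from each group's mean.
#'
#' @param g1,g2 Numeric vectors, each with at least 2 values.
#' @return A list with `statistic` (F), `df1`, `df2` and `p_value`. When
#'   both groups have zero spread the statistic is degenerate and the
#'   p-value is 1, with a warning.
#' @export
levene_test <- function(g1, g2) {
  g1 <- as.numeric(g1); g2 <- as.numeric(g2)
  if (length(g1) < 2L || length(g2) < 2L) stop("each group needs n >= 2")
  z1 <- abs(g1 - mean(g1)); z2 <- abs(g2 - mean(g2))
  n1 <- length(z1); n2 <- length(z2); N <- n1 + n2
  zb1 <- mean(z1); zb2 <- mean(z2)
  zb <- (n1 * zb1 + n2 * zb2) / N
  between <- n1 * (zb1 - zb)^2 + n2 * (zb2 - zb)^2
  within <- sum((z1 - zb1)^2) + sum((z2 - zb2)^2)
  if (within == 0) {
    if (between == 0) {
      warning("zero spread in both groups; Levene statistic degenerate")
      return(list(statistic = 0, df1 = 1L, df2 = N - 2L, p_value = 1))
    }
    return(list(statistic = Inf, df1 = 1L, df2 = N - 2L, p_value = 0))
  }
  stat <- (N - 2L) * between / within
  list(statistic = stat, df1 = 1L, df2 = N - 2L,
       p_value = stats::pf(stat, 1L, N - 2L, lower.tail = FALSE))
}

#' One-tailed Welch two-sample t-test
#'
#' Unequal-variance t statistic with Satterthwaite degrees of freedom;
#' the one-tailed p-value tests the alternative `mean(g1) > mean(g2)`.
#'
#' @param g1,g2 Numeric vectors, each with at least 2 values.
#' @return A list with `statistic`, `df` and `p_value`.
#' @export
welch_t_one_tailed <- function(g1, g2) {
  g1 <- as.numeric(g1); g2 <- as.numeric(g2)
  if (length(g1) < 2L || length(g2) < 2L) stop("each group needs n >= 2")
  n1 <- length(g1); n2 <- length(g2)
  v1 <- stats::var(g1) / n1; v2 <- stats::var(g2) / n2
  se2 <- v1 + v2
  if (se2 == 0) {
    return(list(statistic = 0, df = n1 + n2 - 2L, p_value = 0.5))
  }
  t <- (mean(g1) - mean(g2)) / sqrt(se2)
  df <- se2^2 / (v1^2 / (n1 - 1L) + v2^2 / (n2 - 1L))
  list(statistic = t, df = df,
       p_value = stats::pt(t, df, lower.tail = FALSE))
}

#' Compare the residual magnitudes of two onset models
#'
#' Tests whether the diagnostic-sizing fit predicts age at onset worse
#' than the clone-sequencing fit: a Levene pre-test on the absolute
#' residuals (motivating the unequal-variance t), then a one-tailed
#' Welch t-test of H0 "mean |residual| of the sizing fit is not greater
#' than that of the sequencing fit".
#'
#' @param fit_sizing,fit_sequencing [ols_fit()] results for the two
#'   predictors.
#' @return A list of class `comparison_result` with `levene_P`,
#'   `welch_one_tailed_P`, and `mean_abs_residuals` (named numeric,
#'   sizing and sequencing).
#' @export
compare_residual_models <- function(fit_sizing, fit_sequencing) {
  a1 <- abs(fit_sizing$residuals)
  a2 <- abs(fit_sequencing$residuals)
  lev <- levene_test(a1, a2)
  wel <- welch_t_one_tailed(a1, a2)
  structure(
    list(levene_P = lev$p_value,
         welch_one_tailed_P = wel$p_value,
         mean_abs_residuals = c(sizing = mean(a1), sequencing = mean(a2))),
    class = "comparison_result"
  )
}

#' @export
print.comparison_result <- function(x, ...) {
  cat(sprintf(paste0("<comparison_result> mean |residual|: sizing %.3f vs ",
                     "sequencing %.3f\n  Levene P = %.4f; one-tailed Welch ",
                     "P = %.4f\n"),
              x$mean_abs_residuals[["sizing"]],
              x$mean_abs_residuals[["sequencing"]],
              x$levene_P, x$welch_one_tailed_P))
  invisible(x)
}

#' One-sided Fisher's exact test for a 2x2 table
#'
#' Exact upper-tail p-value `P(X >= a)` under the hypergeometric null
#' with the table's margins fixed, summed by direct enumeration with
#' log-factorials. The one-sided tail is the convention used for
#' comparing interruption prevalence between cohorts.
#'
#' @param a,b First row of the table (e.g. interrupted / uninterrupted
#'   in this cohort).
#' @param c,d Second row (reference cohort).
#' @return The one-sided p-value.
#' @examples
#' fisher_exact_one_sided(4, 31, 1, 16) # 0.467
#' @export
fisher_exact_one_sided <- function(a, b, c, d) {
  counts <- c(a, b, c, d)
  if (any(counts < 0) || any(counts != floor(counts))) {
    stop("table entries must be non-negative integers")
  }
  r1 <- a + b; c1 <- a + c; N <- a + b + c + d
  if (r1 == 0L || c1 == 0L || r1 == N || c1 == N) {
    # a is forced by the margins; the observed table is the only table
    return(1)
  }
  hi <- min(r1, c1)
  xs <- a:hi
  logp <- lchoose(r1, xs) + lchoose(N - r1, c1 - xs) - lchoose(N, c1)
  min(1, sum(exp(logp)))
}
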