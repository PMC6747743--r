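#' ANCOVA adjusted group means at a stated covariate value
#'
#' Fits the common-slope model `y ~ group + x` by ordinary least squares
#' and reports each group's model-predicted (adjusted, "marginal") mean
#' at the covariate value `eval_at`:
#' `adj_g = ybar_g + b * (eval_at - xbar_g)`, with standard error
#' `SE_g = sqrt(MSE * (1/n_g + (xbar_g - eval_at)^2 / Sxx_within))` and a
#' t confidence interval on `n - k - 1` residual degrees of freedom. The
#' partial F for the group factor compares the full model against the
#' covariate-only model.
#'
#' The default evaluation point is `eval_at = 0`: when the outcome is
#' change in age-difference and the covariate is the baseline
#' age-difference, the adjusted means are then the expected change for a
#' participant whose epigenetic and chronological ages initially agree.
#' Group *contrasts* do not depend on `eval_at` (see [group_contrast()]).
#'
#' @param y numeric outcome.
#' @param x numeric covariate.
#' @param groups factor (or coercible) of group labels.
#' @param eval_at covariate value at which adjusted means are reported.
#' @param conf_level confidence level for the t intervals.
#' @return An `ancova_fit` list: `slope`, `eval_at`, `df`, `mse`,
#'   `sxx_within`, `f` / `f_df` / `p` for the group factor, and a
#'   data frame `means` with columns `group, n, y_mean, x_mean, adjusted,
#'   se, ci_lo, ci_hi`.
#' @export
ancova_adjusted_means <- function(y, x, groups, eval_at = 0,
                                  conf_level = 0.95) {
  if (!is.finite(eval_at)) stop("eval_at must be finite")
  groups <- droplevels(as.factor(groups))
  k <- nlevels(groups)
  n <- length(y)
  if (k < 2) stop("need at least two groups")
  if (n <= k + 1) stop("need n > n_groups + 1 observations")
  full <- stats::lm(y ~ groups + x)
  if (any(is.na(stats::coef(full)))) {
    stop("singular design: covariate confounded with groups")
  }
  reduced <- stats::lm(y ~ x)
  b <- unname(stats::coef(full)["x"])
  df <- n - k - 1
  mse <- sum(stats::residuals(full)^2) / df
  xbar <- tapply(x, groups, mean)
  ybar <- tapply(y, groups, mean)
  ng <- as.integer(table(groups))
  sxx <- sum((x - xbar[groups])^2)
  adj <- ybar + b * (eval_at - xbar)
  se <- sqrt(mse * (1 / ng + (xbar - eval_at)^2 / sxx))
  tcrit <- stats::qt(1 - (1 - conf_level) / 2, df)
  sse_r <- sum(stats::residuals(reduced)^2)
  sse_f <- sum(stats::residuals(full)^2)
  f <- ((sse_r - sse_f) / (k - 1)) / mse
  structure(list(
    slope = b, eval_at = eval_at, df = df, mse = mse, sxx_within = sxx,
    f = f, f_df = c(k - 1, df), p = stats::pf(f, k - 1, df,
                                              lower.tail = FALSE),
    conf_level = conf_level,
    means = data.frame(group = levels(groups), n = ng,
                       y_mean = as.numeric(ybar), x_mean = as.numeric(xbar),
                       adjusted = as.numeric(adj), se = as.numeric(se),
                       ci_lo = as.numeric(adj - tcrit * se),
                       ci_hi = as.numeric(adj + tcrit * se),
                       stringsAsFactors = FALSE)),
    class = "ancova_fit")
}

#' @export
print.ancova_fit <- function(x, ...) {
  cat(sprintf(
    "ANCOVA (common slope %.3f), adjusted means at covariate = %g\n",
    x$slope, x$eval_at))
  m <- x$means
  for (i in seq_len(nrow(m))) {
    cat(sprintf("  %-6s %6.2f  [%.2f; %.2f]  (n = %d)\n", m$group[i],
                m$adjusted[i], m$ci_lo[i], m$ci_hi[i], m$n[i]))
  }
  cat(sprintf("  group F(%d,%d) = %.2f, p = %.3f\n",
              x$f_df[1], x$f_df[2], x$f, x$p))
  invisible(x)
}

#' Adjusted-mean contrast between two groups
#'
#' `adj(g1) - adj(g2) = (ybar_1 - ybar_2) - b * (xbar_1 - xbar_2)`, which
#' is independent of the evaluation point, with
#' `SE = sqrt(MSE * (1/n_1 + 1/n_2 + (xbar_1 - xbar_2)^2 / Sxx_within))`
#' and a t interval on the residual degrees of freedom.
#'
#' @param fit an [ancova_adjusted_means()] result.
#' @param g1,g2 group labels; the estimate is `g1 - g2`.
#' @return List with `estimate`, `se`, `ci_lo`, `ci_hi`, `df`.
#' @export
group_contrast <- function(fit, g1, g2) {
  m <- fit$means
  i1 <- match(g1, m$group); i2 <- match(g2, m$group)
  if (is.na(i1) || is.na(i2)) stop("unknown group label")
  est <- m$adjusted[i1] - m$adjusted[i2]
  se <- sqrt(fit$mse * (1 / m$n[i1] + 1 / m$n[i2] +
                          (m$x_mean[i1] - m$x_mean[i2])^2 / fit$sxx_within))
  tcrit <- stats::qt(1 - (1 - fit$conf_level) / 2, fit$df)
  list(estimate = est, se = se,
       ci_lo = est - tcrit * se, ci_hi = est + tcrit * se, df = fit$df)
}
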