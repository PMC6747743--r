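# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: the SRI oracle enumerates pairs one by one, the
# deconvolution oracle searches the simplex on a grid, and the ANCOVA
# oracle solves the normal equations directly.

oracle_sri <- function(grid, probabilistic = FALSE) {
  vals <- c()
  for (d in seq_len(nrow(grid) - 1)) {
    for (j in seq_len(ncol(grid))) {
      p1 <- grid[d, j]; p2 <- grid[d + 1, j]
      if (is.na(p1) || is.na(p2)) next
      vals <- c(vals, if (probabilistic) p1 * p2 + (1 - p1) * (1 - p2)
                else as.numeric(p1 == p2))
    }
  }
  -100 + 200 * mean(vals)
}

# grid search over {w >= 0, sum(w) <= 1} at the given step
oracle_deconv <- function(x, R, step = 0.01) {
  k <- ncol(R)
  gr <- seq(0, 1, by = step)
  best <- NULL; best_val <- Inf
  combos <- do.call(expand.grid, rep(list(gr), k - 1))
  for (i in seq_len(nrow(combos))) {
    head <- as.numeric(combos[i, ])
    if (sum(head) > 1 + 1e-9) next
    for (last in gr[gr <= 1 - sum(head) + 1e-9]) {
      w <- c(head, last)
      val <- sum((x - R %*% w)^2)
      if (val < best_val) { best_val <- val; best <- w }
    }
  }
  best / sum(best)
}

oracle_ancova <- function(y, x, g, eval_at = 0) {
  g <- droplevels(as.factor(g))
  X <- cbind(stats::model.matrix(~ g - 1), x)
  beta <- solve(crossprod(X), crossprod(X, y))
  k <- nlevels(g)
  b <- beta[k + 1]
  resid <- y - X %*% beta
  df <- length(y) - k - 1
  mse <- sum(resid^2) / df
  xbar <- tapply(x, g, mean)
  ng <- as.numeric(table(g))
  sxx <- sum((x - xbar[g])^2)
  adj <- as.numeric(beta[1:k]) + b * eval_at
  se <- sqrt(mse * (1 / ng + (as.numeric(xbar) - eval_at)^2 / sxx))
  list(adjusted = adj, se = se, slope = b, mse = mse, df = df)
}

# one-row diary helpers for SRI tests
one_day <- function(bed, wake, awake = 0, nap = 0, n_awak = as.integer(awake > 0),
                    n_naps = as.integer(nap > 0), pid = "p1", day = 0L) {
  sleep_diary(pid, day, bed, wake, n_awakenings = n_awak, awake_min = awake,
              n_naps = n_naps, nap_min = nap)
}

repeat_days <- function(n, bed, wake, awake = 0, nap = 0, pid = "p1") {
  sleep_diary(rep(pid, n), seq_len(n) - 1L, rep(bed, n), rep(wake, n),
              n_awakenings = as.integer(awake > 0), awake_min = awake,
              n_naps = as.integer(nap > 0), nap_min = nap)
}

ks_stat <- function(a, b) {
  suppressWarnings(unname(stats::ks.test(a, b)$statistic))
}
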