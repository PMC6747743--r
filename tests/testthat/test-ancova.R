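random_instance <- function(seed, k = 3, n = 15) {
  set.seed(seed)
  g <- factor(sample(letters[1:k], n, replace = TRUE))
  while (nlevels(droplevels(g)) < k) {
    g <- factor(sample(letters[1:k], n, replace = TRUE))
  }
  x <- rnorm(n)
  y <- rnorm(n) + as.numeric(g) + 0.5 * x
  list(y = y, x = x, g = g)
}

test_that("adjusted means match the normal-equations oracle", {
  for (seed in 1:100) {
    inst <- random_instance(seed)
    ev <- rnorm(1)
    fit <- ancova_adjusted_means(inst$y, inst$x, inst$g, eval_at = ev)
    o <- oracle_ancova(inst$y, inst$x, inst$g, eval_at = ev)
    expect_equal(fit$means$adjusted, o$adjusted, tolerance = 1e-8)
    expect_equal(fit$means$se, o$se, tolerance = 1e-8)
    expect_equal(fit$slope, o$slope, tolerance = 1e-8)
    expect_equal(fit$mse, o$mse, tolerance = 1e-8)
  }
})

test_that("adjusted means and CIs match emmeans on a reference fit", {
  inst <- random_instance(7)
  fit <- ancova_adjusted_means(inst$y, inst$x, inst$g, eval_at = 0.3)
  lmfit <- lm(y ~ g + x, data = data.frame(inst))
  em <- summary(emmeans::emmeans(lmfit, ~g, at = list(x = 0.3)))
  expect_equal(fit$means$adjusted, em$emmean, tolerance = 1e-8)
  expect_equal(fit$means$se, em$SE, tolerance = 1e-8)
  expect_equal(fit$means$ci_lo, em$lower.CL, tolerance = 1e-8)
  expect_equal(fit$means$ci_hi, em$upper.CL, tolerance = 1e-8)
  ct <- group_contrast(fit, "a", "b")
  emc <- confint(emmeans::contrast(
    emmeans::emmeans(lmfit, ~g), method = list(`a-b` = c(1, -1, 0))))
  expect_equal(ct$estimate, emc$estimate, tolerance = 1e-8)
  expect_equal(c(ct$ci_lo, ct$ci_hi), c(emc$lower.CL, emc$upper.CL),
               tolerance = 1e-8)
})

test_that("a zero-slope construction returns raw group means everywhere", {
  g <- factor(rep(c("a", "b", "c"), each = 5))
  x <- rep(seq(-2, 2, 1), 3)
  y <- rep(c(1, 3, 6), each = 5) + rep(c(-1, 1, 0, 1, -1) * 0, 3)
  for (ev in c(-3, 0, 2.5)) {
    fit <- ancova_adjusted_means(y, x, g, eval_at = ev)
    expect_equal(fit$slope, 0, tolerance = 1e-12)
    expect_equal(fit$means$adjusted, c(1, 3, 6), tolerance = 1e-10)
  }
})

test_that("an exact linear construction is recovered exactly", {
  g <- factor(rep(c("a", "b", "c"), times = c(5, 6, 5)))
  set.seed(99)
  x <- rnorm(16)
  offs <- c(a = 0, b = 1, c = 3)
  y <- 2 - 0.5 * x + offs[as.character(g)]
  fit <- ancova_adjusted_means(y, x, g, eval_at = 0)
  expect_equal(fit$slope, -0.5, tolerance = 1e-10)
  expect_equal(fit$means$adjusted, unname(2 + offs), tolerance = 1e-10)
  expect_equal(fit$mse, 0, tolerance = 1e-12)
})

test_that("contrasts do not depend on the evaluation point", {
  inst <- random_instance(23)
  ref <- group_contrast(
    ancova_adjusted_means(inst$y, inst$x, inst$g, eval_at = 0), "a", "c")
  set.seed(1)
  for (ev in rnorm(8, sd = 5)) {
    ct <- group_contrast(
      ancova_adjusted_means(inst$y, inst$x, inst$g, eval_at = ev), "a", "c")
    expect_equal(ct$estimate, ref$estimate, tolerance = 1e-10)
    expect_equal(ct$se, ref$se, tolerance = 1e-10)
  }
  expect_error(group_contrast(
    ancova_adjusted_means(inst$y, inst$x, inst$g), "a", "zz"), "unknown")
})

test_that("adjusted means at the pooled covariate mean average to the grand mean", {
  inst <- random_instance(31)
  fit <- ancova_adjusted_means(inst$y, inst$x, inst$g,
                               eval_at = mean(inst$x))
  wavg <- sum(fit$means$adjusted * fit$means$n) / sum(fit$means$n)
  expect_equal(wavg, mean(inst$y), tolerance = 1e-10)
})

test_that("fitting the Time-2 level instead of the change shifts only the slope", {
  co <- pilot_cohort()
  d1 <- co$epi_t1 - co$chron_t1
  d2 <- co$epi_t2 - co$chron_t2
  grp <- cross_groups(
    classify_duration(setNames(co$tst, co$participant_id)),
    classify_regularity(setNames(co$sri, co$participant_id))$labels)
  f_change <- ancova_adjusted_means(d2 - d1, d1, grp)
  f_level <- ancova_adjusted_means(d2, d1, grp)
  expect_equal(f_level$slope, f_change$slope + 1, tolerance = 1e-10)
  expect_equal(f_level$mse, f_change$mse, tolerance = 1e-10)
  expect_equal(f_level$f, f_change$f, tolerance = 1e-10)
  expect_equal(f_level$means$adjusted, f_change$means$adjusted,
               tolerance = 1e-10)   # at eval_at = 0 the two models agree
})

test_that("degenerate designs are refused", {
  g <- factor(rep(c("a", "b"), each = 4))
  x <- as.numeric(g)                       # covariate confounded with group
  y <- rnorm(8)
  expect_error(ancova_adjusted_means(y, x, g), "singular")
  expect_error(
    ancova_adjusted_means(rnorm(3), rnorm(3), factor(c("a", "b", "a"))),
    "n >")
  expect_error(ancova_adjusted_means(y, rnorm(8), g, eval_at = NA),
               "finite")
})
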