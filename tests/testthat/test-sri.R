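test_that("diary_to_grid spreads diary totals over the right epochs", {
  g <- diary_to_grid(repeat_days(2, 23, 31), epoch_min = 60L)
  expect_equal(dim(g), c(2, 24))
  expect_equal(sum(g[1, ] == 1), 8)   # the 8 night hours
  expect_equal(sum(g[1, ] == 0), 16)  # the 16 wake hours
  # awakenings dilute the night uniformly: 48 min over 8 h -> p = 0.90
  g <- diary_to_grid(repeat_days(2, 23, 31, awake = 48), epoch_min = 60L)
  expect_equal(unique(g[1, g[1, ] > 0.5]), 0.9)
  # naps spread over the 16-h wake period: 96 min -> p = 0.10
  g <- diary_to_grid(repeat_days(2, 23, 31, nap = 96), epoch_min = 60L)
  expect_equal(unique(round(g[1, g[1, ] < 0.5], 10)), 0.1)
  # an epoch straddling the bedtime boundary gets the duration blend
  g <- diary_to_grid(repeat_days(2, 23.5, 31), epoch_min = 60L)
  expect_equal(g[1, 12], 0.5)          # epoch [23, 24): half asleep
  # missing day rows are all NA
  d <- sleep_diary("p1", 0:1, c(23, NA), c(31, NA),
                   missing = c(FALSE, TRUE))
  g <- diary_to_grid(d, epoch_min = 60L)
  expect_true(all(is.na(g[2, ])))
  expect_error(diary_to_grid(repeat_days(2, 23, 31), epoch_min = 7L),
               "divisor")
})

test_that("opposing-state weighting stores the literal reading", {
  g <- diary_to_grid(repeat_days(2, 23, 31, awake = 48, nap = 96),
                     epoch_min = 60L, weighting = "opposing")
  expect_equal(unique(round(g[1, 13:19], 10)), 0.1)  # awake fraction
  expect_equal(unique(round(g[1, 1:11], 10)), 0.1)   # napping fraction
})

test_that("binary SRI matches its definition on canonical grids", {
  g <- diary_to_grid(repeat_days(5, 23, 31), epoch_min = 30L)
  s <- sri_binary(g)
  expect_equal(s$value, 100)
  expect_equal(s$n_pairs_total, 4 * 48)
  # alternating complemented days disagree at every epoch pair
  flip <- matrix(rep(c(0, 1), each = 24), nrow = 2, byrow = TRUE)
  flip <- flip[rep(1:2, 3), ]
  expect_equal(sri_binary(flip)$value, -100)
  # iid Bernoulli(1/2) days: expectation 0
  set.seed(42)
  g <- matrix(rbinom(30 * 1440, 1, 0.5), nrow = 30)
  expect_lt(abs(sri_binary(g)$value), 2)
  expect_error(sri_binary(matrix(0.5, 2, 4)), "binary")
  expect_error(sri_binary(matrix(NA_real_, 2, 4)), "insufficient-data")
})

test_that("probabilistic SRI has the closed-form fixed points", {
  expect_equal(sri_probabilistic(matrix(0.5, 4, 6))$value, 0)
  g <- diary_to_grid(repeat_days(4, 23, 31), epoch_min = 60L)
  expect_equal(sri_probabilistic(g)$value, 100)
  # regular schedule, night p = 0.9 / day p = 0.1: -100 + 200(0.81+0.01+...)
  gg <- matrix(rep(c(rep(0.9, 8), rep(0.1, 16)), 3), nrow = 3, byrow = TRUE)
  expect_equal(sri_probabilistic(gg)$value,
               -100 + 200 * (0.9^2 + 0.1^2), tolerance = 1e-9)
})

test_that("probabilistic SRI equals binary SRI on every tiny binary grid", {
  # exhaustive: all 2^6 two-day, three-epoch binary grids
  for (code in 0:63) {
    g <- matrix(as.integer(intToBits(code))[1:6], nrow = 2, byrow = TRUE)
    expected <- oracle_sri(g)
    expect_equal(sri_binary(g)$value, expected)
    expect_equal(sri_probabilistic(g)$value, expected, tolerance = 1e-12)
  }
})

test_that("SRI agrees with the pair enumerator on probabilistic grids", {
  set.seed(11)
  for (i in 1:10) {
    g <- matrix(runif(5 * 8), nrow = 5)
    g[sample(length(g), 4)] <- NA
    s <- sri_probabilistic(g)
    expect_equal(s$value, oracle_sri(g, probabilistic = TRUE),
                 tolerance = 1e-12)
  }
})

test_that("missing days drop exactly their own pairs", {
  set.seed(3)
  g <- matrix(runif(6 * 10), nrow = 6)
  full <- sri_probabilistic(g)
  g2 <- g; g2[3, ] <- NA
  part <- sri_probabilistic(g2)
  # day 3 participates in the (2,3) and (3,4) pair rows
  expect_equal(full$n_pairs_used - part$n_pairs_used, 2 * 10)
  expect_equal(part$n_pairs_total, full$n_pairs_total)
})

test_that("SRI is invariant to a common circular epoch shift", {
  set.seed(5)
  g <- matrix(runif(4 * 12), nrow = 4)
  base <- sri_probabilistic(g)$value
  for (shift in c(1, 5, 11)) {
    gs <- g[, c((shift + 1):12, 1:shift)]
    expect_equal(sri_probabilistic(gs)$value, base, tolerance = 1e-12)
  }
})

test_that("grid CSV export round-trips", {
  d <- sleep_diary("p9", 0:2, c(23, NA, 24.5), c(31, NA, 32),
                   nap_min = c(30, 0, 0), n_naps = c(1L, 0L, 0L),
                   missing = c(FALSE, TRUE, FALSE))
  g <- diary_to_grid(d, epoch_min = 120L)
  path <- withr::local_tempfile(fileext = ".csv")
  write_grid_csv(g, path)
  rows <- utils::read.csv(path)
  expect_equal(nrow(rows), 3 * 12)
  expect_true(all(rows$missing[rows$day == 1] == 1))
  back <- read_grid_csv(path)
  expect_equal(unclass(back)[, ], unclass(g)[, ], tolerance = 1e-12)
  expect_equal(attr(back, "epoch_min"), attr(g, "epoch_min"))
})
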