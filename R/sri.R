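#' Build a sleep-probability grid from a diary
#'
#' Converts one participant's diary into a days-by-epochs matrix of
#' P(asleep). Diaries record nap and awakening totals but not their
#' timing, so within-period probabilities are flat: every epoch of the
#' night sleep period gets `1 - awake_min / (60 * sleep_period_h)` and
#' every epoch of the wake period gets `nap_min / (60 * wake_period_h)`.
#' Epochs straddling a bed/wake boundary get the duration-weighted blend.
#' Missing diary days become all-`NA` rows and are excluded from any SRI
#' computation downstream.
#'
#' Day 0 epoch 0 is anchored at study-start noon; because clock times use
#' the noon-to-noon axis, each night's sleep period falls inside its own
#' row of the grid.
#'
#' @param diary a [sleep_diary()] for a single participant.
#' @param epoch_min epoch length in minutes; must divide 1440. Default 1.
#' @param weighting how diary totals become epoch state values.
#'   `"probability"` (default) stores the probability of being asleep, as
#'   described above. `"opposing"` stores instead the proportion of each
#'   period spent in the opposing state (the awake fraction across the
#'   sleep period, the napping fraction across the wake period) — a
#'   literal reading of "index values multiplied by the proportion of
#'   the period spent in the opposing state". Under the pairwise
#'   agreement statistic this weighting discards the sleep/wake contrast
#'   itself (an unbroken sleeper's nights and days both score near zero),
#'   so it is provided for comparison only.
#' @param strict passed to [validate_diary()].
#' @return A `sleep_grid` object: a D x (1440/epoch_min) numeric matrix of
#'   sleep probabilities in `[0, 1]` (NA rows for missing days), with
#'   attributes `participant_id` and `epoch_min`.
#' @export
diary_to_grid <- function(diary, epoch_min = 1L,
                          weighting = c("probability", "opposing"),
                          strict = TRUE) {
  weighting <- match.arg(weighting)
  diary <- validate_diary(diary, strict = strict)
  if (length(unique(diary$participant_id)) != 1) {
    stop("diary_to_grid expects a single participant's diary")
  }
  epoch_min <- as.integer(epoch_min)
  if (epoch_min <= 0 || 1440L %% epoch_min != 0L) {
    stop("epoch_min must be a positive divisor of 1440")
  }
  m <- 1440L %/% epoch_min
  e_h <- epoch_min / 60
  edges <- 12 + e_h * (0:m)          # epoch boundaries, hours on the axis
  grid <- matrix(NA_real_, nrow = nrow(diary), ncol = m)
  for (i in seq_len(nrow(diary))) {
    if (diary$missing[i]) next
    b <- diary$bedtime_h[i]; w <- diary$waketime_h[i]
    spd <- w - b
    p_sleep <- 1 - diary$awake_min[i] / (60 * spd)
    p_wake <- diary$nap_min[i] / (60 * (24 - spd))
    if (weighting == "opposing") {
      p_sleep <- 1 - p_sleep                # awake fraction of the night
    }
    # fraction of each epoch inside [b, w)
    f <- (pmin(edges[-1], w) - pmax(edges[-(m + 1)], b)) / e_h
    f <- pmin(pmax(f, 0), 1)
    grid[i, ] <- f * p_sleep + (1 - f) * p_wake
  }
  structure(grid,
            participant_id = diary$participant_id[1],
            epoch_min = epoch_min,
            class = c("sleep_grid", "matrix", "array"))
}

sri_pairs <- function(grid) {
  d <- nrow(grid)
  if (d < 2) stop("insufficient-data: SRI needs at least two diary days")
  p1 <- grid[-d, , drop = FALSE]
  p2 <- grid[-1, , drop = FALSE]
  keep <- !is.na(p1) & !is.na(p2)
  list(p1 = p1[keep], p2 = p2[keep], n_total = length(p1))
}

sri_score <- function(agree, n_used, n_total) {
  structure(list(value = -100 + 200 * mean(agree),
                 n_pairs_used = n_used, n_pairs_total = n_total),
            class = "sri_score")
}

#' @export
print.sri_score <- function(x, ...) {
  cat(sprintf("SRI %.2f  (%d of %d epoch pairs used)\n",
              x$value, x$n_pairs_used, x$n_pairs_total))
  invisible(x)
}

#' Sleep Regularity Index (binary form)
#'
#' The standard SRI compares sleep/wake state at epochs 24 h apart on
#' consecutive days: `SRI = -100 + 200 * P(same state)`, so 100 means
#' every day is identical and around 0 means day-to-day state is
#' unrelated. Pairs with a missing member are excluded from numerator and
#' denominator alike.
#'
#' @param grid a [diary_to_grid()] matrix whose entries are 0, 1 or `NA`.
#' @return An `sri_score` with fields `value` (in `[-100, 100]`),
#'   `n_pairs_used` and `n_pairs_total`.
#' @export
sri_binary <- function(grid) {
  pp <- sri_pairs(grid)
  if (length(pp$p1) == 0) stop("insufficient-data: no valid epoch pairs")
  if (!all(pp$p1 %in% c(0, 1)) || !all(pp$p2 %in% c(0, 1))) {
    stop("sri_binary requires a binary grid; use sri_probabilistic")
  }
  sri_score(as.numeric(pp$p1 == pp$p2), length(pp$p1), pp$n_total)
}

#' Sleep Regularity Index (probabilistic form)
#'
#' Extension of the SRI to grids of sleep *probabilities*, for diaries
#' that report how much of the night was spent awake and how much of the
#' day was napped but not when. Per pair of epochs 24 h apart the
#' same-state probability is `a = p1*p2 + (1-p1)*(1-p2)` — the chance two
#' independent states drawn with those probabilities agree — and
#' `SRI = -100 + 200 * mean(a)`. On a strictly 0/1 grid this reduces
#' exactly to [sri_binary()]. A grid at p = 0.5 everywhere scores 0, the
#' no-information fixed point.
#'
#' @inheritParams sri_binary
#' @param grid probabilities in `[0, 1]` or `NA`.
#' @return An `sri_score`.
#' @export
sri_probabilistic <- function(grid) {
  pp <- sri_pairs(grid)
  if (length(pp$p1) == 0) stop("insufficient-data: no valid epoch pairs")
  if (any(pp$p1 < 0 | pp$p1 > 1) || any(pp$p2 < 0 | pp$p2 > 1)) {
    stop("grid entries must be probabilities in [0, 1]")
  }
  a <- pp$p1 * pp$p2 + (1 - pp$p1) * (1 - pp$p2)
  sri_score(a, length(a), pp$n_total)
}

#' Export / import a sleep grid as tidy CSV
#'
#' One row per (day, epoch) with the sleep probability, `NA` probabilities
#' flagged as missing — the long format raster-plot tools consume.
#'
#' @param grid a [diary_to_grid()] grid.
#' @param path CSV path.
#' @return `write_grid_csv` returns `path` invisibly; `read_grid_csv`
#'   returns a `sleep_grid`.
#' @export
write_grid_csv <- function(grid, path) {
  d <- expand.grid(epoch = seq_len(ncol(grid)) - 1L,
                   day = seq_len(nrow(grid)) - 1L)[, c("day", "epoch")]
  d$p_asleep <- as.vector(t(unclass(grid)))
  d$missing <- as.integer(is.na(d$p_asleep))
  d$participant_id <- attr(grid, "participant_id")
  d$epoch_min <- attr(grid, "epoch_min")
  utils::write.csv(d, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' @rdname write_grid_csv
#' @export
read_grid_csv <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  days <- sort(unique(d$day))
  m <- length(unique(d$epoch))
  grid <- matrix(NA_real_, nrow = length(days), ncol = m)
  grid[cbind(match(d$day, days), d$epoch + 1L)] <- d$p_asleep
  structure(grid,
            participant_id = as.character(d$participant_id[1]),
            epoch_min = as.integer(d$epoch_min[1]),
            class = c("sleep_grid", "matrix", "array"))
}
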