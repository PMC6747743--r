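#' Construct a sleep diary table
#'
#' A diary is a plain data frame with one row per participant-day. Clock
#' times live on a noon-to-noon axis: hours after midnight of the diary
#' date, in `[12, 36)`, so `25.85` means 01:51 the next calendar day and
#' `23.0` means 11 pm. The axis places every night's sleep period inside a
#' single diary day, so no midnight wraparound arithmetic is ever needed.
#'
#' @param participant_id character vector of participant identifiers.
#' @param day_index integer study day, starting at 0, contiguous per
#'   participant.
#' @param bedtime_h,waketime_h bed and rise times in hours on the
#'   noon-to-noon axis (`[12, 36)`); `waketime_h - bedtime_h` is the sleep
#'   period and must lie in `(0, 24)` for non-missing days.
#' @param n_awakenings,awake_min number and total minutes of night
#'   awakenings (totals only; the diary does not record their timing).
#' @param n_naps,nap_min number and total minutes of daytime naps.
#' @param missing logical; `TRUE` marks a day with no diary entry. Missing
#'   days keep their row (with `NA` fields) so day indexing stays contiguous.
#' @return A `data.frame` with class `c("sleep_diary", "data.frame")`.
#' @seealso [validate_diary()], [daily_tst()], [diary_to_grid()]
#' @export
sleep_diary <- function(participant_id, day_index, bedtime_h, waketime_h,
                        n_awakenings = 0L, awake_min = 0, n_naps = 0L,
                        nap_min = 0, missing = FALSE) {
  d <- data.frame(
    participant_id = as.character(participant_id),
    day_index = as.integer(day_index),
    bedtime_h = as.numeric(bedtime_h),
    waketime_h = as.numeric(waketime_h),
    n_awakenings = as.integer(n_awakenings),
    awake_min = as.numeric(awake_min),
    n_naps = as.integer(n_naps),
    nap_min = as.numeric(nap_min),
    missing = as.logical(missing),
    stringsAsFactors = FALSE
  )
  d[d$missing, c("bedtime_h", "waketime_h")] <- NA_real_
  class(d) <- c("sleep_diary", "data.frame")
  d
}

#' Validate a sleep diary
#'
#' Checks the per-day invariants: times on the noon-to-noon axis, sleep
#' period in `(0, 24)` hours, awakening minutes no longer than the sleep
#' period, nap minutes no longer than the wake period, contiguous
#' `day_index` per participant.
#'
#' @param diary a [sleep_diary()] data frame.
#' @param strict if `TRUE` (default) violations are errors; if `FALSE`,
#'   out-of-range awakening/nap minutes are clamped to their admissible
#'   maximum with a warning (time-axis violations are always errors).
#' @return The (possibly clamped) diary, invisibly usable downstream.
#' @export
validate_diary <- function(diary, strict = TRUE) {
  req <- c("participant_id", "day_index", "bedtime_h", "waketime_h",
           "n_awakenings", "awake_min", "n_naps", "nap_min", "missing")
  miss <- setdiff(req, names(diary))
  if (length(miss) > 0) {
    stop("diary is missing columns: ", paste(miss, collapse = ", "))
  }
  for (pid in unique(diary$participant_id)) {
    di <- diary$day_index[diary$participant_id == pid]
    if (!all(di == seq(min(di), length.out = length(di)))) {
      stop("day_index not strictly increasing and contiguous for participant ",
           pid)
    }
  }
  ok <- !diary$missing
  if (any(ok)) {
    b <- diary$bedtime_h[ok]; w <- diary$waketime_h[ok]
    if (any(!is.finite(b)) || any(!is.finite(w))) {
      stop("non-missing days must have finite bed/wake times")
    }
    if (any(b < 12 | b >= 36)) {
      stop("bedtime_h outside [12, 36) on the noon-to-noon axis")
    }
    spd <- w - b
    if (any(spd <= 0 | spd >= 24)) {
      stop("sleep-period duration (waketime_h - bedtime_h) outside (0, 24)")
    }
    if (any(diary$awake_min[ok] < 0) || any(diary$nap_min[ok] < 0) ||
        any(diary$n_awakenings[ok] < 0) || any(diary$n_naps[ok] < 0)) {
      stop("negative awakening/nap counts or minutes")
    }
    awake_max <- 60 * spd
    nap_max <- 60 * (24 - spd)
    over_a <- diary$awake_min[ok] > awake_max
    over_n <- diary$nap_min[ok] > nap_max
    if (any(over_a) || any(over_n)) {
      if (strict) {
        stop("awake_min exceeds the sleep period or nap_min exceeds the ",
             "wake period; rerun with strict = FALSE to clamp")
      }
      warning("clamping out-of-range awake_min/nap_min on ",
              sum(over_a) + sum(over_n), " day(s)")
      am <- diary$awake_min[ok]; am[over_a] <- awake_max[over_a]
      nm <- diary$nap_min[ok]; nm[over_n] <- nap_max[over_n]
      diary$awake_min[ok] <- am
      diary$nap_min[ok] <- nm
    }
  }
  diary
}

#' Daily total sleep time
#'
#' TST for one diary day is the night sleep-period duration minus total
#' night-awakening minutes plus total nap minutes, clamped at zero:
#' `TST = (waketime - bedtime) - awake_min/60 + nap_min/60`. Wake after
#' sleep onset is excluded and naps count toward total sleep, the usual
#' reading of "total sleep time" for diary data.
#'
#' @param diary a validated [sleep_diary()].
#' @param allow_missing if `FALSE` (default) a missing day is an error
#'   ("missing-day"); if `TRUE`, missing days yield `NA`.
#' @return Numeric vector of hours in `[0, 24]`, one per diary row.
#' @export
daily_tst <- function(diary, allow_missing = FALSE) {
  diary <- validate_diary(diary)
  if (!allow_missing && any(diary$missing)) {
    stop("missing-day: daily TST requested for a missing diary day")
  }
  tst <- with(diary, (waketime_h - bedtime_h) - awake_min / 60 + nap_min / 60)
  tst <- pmin(pmax(tst, 0), 24)
  tst[diary$missing] <- NA_real_
  tst
}

#' Average total sleep time over a diary
#'
#' Mean of [daily_tst()] over non-missing days; missing days are excluded,
#' never imputed.
#'
#' @inheritParams daily_tst
#' @return Mean TST in hours.
#' @export
average_tst <- function(diary) {
  diary <- validate_diary(diary)
  tst <- daily_tst(diary, allow_missing = TRUE)
  if (all(is.na(tst))) stop("no-data: all diary days are missing")
  mean(tst, na.rm = TRUE)
}

#' Mean clock time on the noon-to-noon axis
#'
#' Arithmetic mean of clock times represented in `[12, 36)`. Because the
#' axis is unwrapped, the mean of 23:30 and 00:30 is correctly 24:00, not
#' noon. The display form reduces the mean modulo 24 hours; some published
#' summaries instead print the raw-axis value for times just after
#' midnight of the *previous* convention (e.g. a bedtime shown as 24.77),
#' which `display = "raw"` preserves.
#'
#' @param values numeric hours, each in `[12, 36)`.
#' @param display one of `"none"` (return the unwrapped mean), `"mod24"`
#'   (mean modulo 24, rounded to 2 dp), `"raw"` (unwrapped mean rounded to
#'   2 dp).
#' @return Mean time in hours under the requested convention.
#' @export
mean_clock_time <- function(values, display = c("none", "mod24", "raw")) {
  display <- match.arg(display)
  if (length(values) == 0) stop("empty clock-time vector")
  if (any(values < 12 | values >= 36)) {
    stop("clock times must lie in [12, 36) on the noon-to-noon axis")
  }
  m <- mean(values)
  switch(display,
         none = m,
         mod24 = round(m %% 24, 2),
         raw = round(m, 2))
}

#' Read / write the diary CSV format
#'
#' The on-disk dialect is UTF-8 CSV with a header row and columns
#' `participant_id, day_index, bedtime_h, waketime_h, n_awakenings,
#' awake_min, n_naps, nap_min, missing` (times on the noon-to-noon axis;
#' missing days carry empty time cells and `missing = 1`).
#'
#' @param path file path.
#' @param diary a [sleep_diary()] data frame.
#' @param strict passed to [validate_diary()].
#' @return `read_diary_csv` returns a validated `sleep_diary`;
#'   `write_diary_csv` returns `path` invisibly.
#' @export
read_diary_csv <- function(path, strict = TRUE) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (nrow(raw) == 0) stop("no-data: diary file has no rows")
  d <- sleep_diary(raw$participant_id, raw$day_index, raw$bedtime_h,
                   raw$waketime_h, raw$n_awakenings, raw$awake_min,
                   raw$n_naps, raw$nap_min, as.logical(raw$missing) |
                     raw$missing == 1)
  validate_diary(d, strict = strict)
}

#' @rdname read_diary_csv
#' @export
write_diary_csv <- function(diary, path) {
  out <- as.data.frame(diary)
  out$missing <- as.integer(out$missing)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Per-participant diary summaries
#'
#' One row per participant: day counts, mean TST, mean bed/wake clock
#' times, and (optionally) an SRI value supplied by the caller. Mirrors
#' the usual cohort descriptive table; numeric columns are rounded to
#' 2 dp when `round2 = TRUE`.
#'
#' @param diary a [sleep_diary()] covering one or more participants.
#' @param sri optional named numeric vector of SRI scores keyed by
#'   participant id.
#' @param round2 round summary columns to 2 decimal places.
#' @return data frame with columns `participant_id, n_days, n_missing,
#'   mean_tst_h, mean_bedtime_h, mean_waketime_h, sri`.
#' @export
summarize_participants <- function(diary, sri = NULL, round2 = TRUE) {
  diary <- validate_diary(diary)
  ids <- unique(diary$participant_id)
  rows <- lapply(ids, function(pid) {
    d <- diary[diary$participant_id == pid, ]
    ok <- !d$missing
    data.frame(
      participant_id = pid,
      n_days = nrow(d),
      n_missing = sum(d$missing),
      mean_tst_h = average_tst(d),
      mean_bedtime_h = mean_clock_time(d$bedtime_h[ok]),
      mean_waketime_h = mean_clock_time(d$waketime_h[ok]),
      sri = if (!is.null(sri) && pid %in% names(sri)) unname(sri[pid])
            else NA_real_,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  if (round2) {
    num <- c("mean_tst_h", "mean_bedtime_h", "mean_waketime_h", "sri")
    out[num] <- lapply(out[num], round, 2)
  }
  out
}
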