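#' The packaged pilot cohort
#'
#' Summary data for the 12-participant pilot cohort that motivates this
#' package: first-year college women tracked with a daily online sleep
#' diary across the first nine weeks of a semester, with blood drawn at
#' the start (Time 1) and end (Time 2) of the interval and epigenetic
#' ages scored from 450K methylation arrays.
#'
#' `pilot_sleep()` returns the per-participant sleep summaries: Hispanic
#' ethnicity indicator, diary-derived SRI, average TST (hours), and mean
#' wake/bed clock times as conventionally printed (mornings after
#' midnight in `[0, 12)`; bedtimes before midnight kept on the raw
#' noon-to-noon axis, e.g. 24.77 = 00:46).
#'
#' `pilot_aging()` returns chronological age plus epigenetic ages under
#' two scorings (a Horvath-style clock and GrimAge) at both timepoints;
#' rows align with `pilot_sleep()` by participant.
#'
#' `pilot_cohort()` merges the two into the analysis-ready cohort layout
#' used throughout the statistics module.
#'
#' @param clock which epigenetic-age scoring to place in the `epi_*`
#'   columns of the cohort table.
#' @return Data frames; `pilot_cohort()` has columns `participant_id,
#'   chron_t1, chron_t2, epi_t1, epi_t2, tst, sri`.
#' @export
pilot_sleep <- function() {
  utils::read.csv(system.file("extdata", "pilot_sleep.csv",
                              package = "somnoclock"),
                  stringsAsFactors = FALSE)
}

#' @rdname pilot_sleep
#' @export
pilot_aging <- function() {
  utils::read.csv(system.file("extdata", "pilot_aging.csv",
                              package = "somnoclock"),
                  stringsAsFactors = FALSE)
}

#' @rdname pilot_sleep
#' @export
pilot_cohort <- function(clock = c("horvath", "grimage")) {
  clock <- match.arg(clock)
  s <- pilot_sleep()
  a <- pilot_aging()
  data.frame(participant_id = as.character(s$participant_id),
             chron_t1 = a$chron_t1, chron_t2 = a$chron_t2,
             epi_t1 = a[[paste0(clock, "_t1")]],
             epi_t2 = a[[paste0(clock, "_t2")]],
             tst = s$tst, sri = s$sri,
             stringsAsFactors = FALSE)
}

#' Read / write the cohort CSV layout
#'
#' Columns `participant_id, chron_t1, chron_t2, epi_t1, epi_t2, tst, sri`.
#'
#' @param path CSV file.
#' @param cohort cohort data frame.
#' @return `read_cohort_csv` returns the cohort data frame.
#' @export
read_cohort_csv <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("participant_id", "chron_t1", "chron_t2", "epi_t1", "epi_t2",
           "tst", "sri")
  miss <- setdiff(req, names(d))
  if (length(miss) > 0) {
    stop("cohort file missing columns: ", paste(miss, collapse = ", "))
  }
  d$participant_id <- as.character(d$participant_id)
  if (anyDuplicated(d$participant_id)) stop("duplicate participant ids")
  if (any(d$chron_t1 <= 0 | d$chron_t2 <= 0)) stop("ages must be positive")
  d[req]
}

#' @rdname read_cohort_csv
#' @export
write_cohort_csv <- function(cohort, path) {
  utils::write.csv(cohort, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
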