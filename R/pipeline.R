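#' Full cohort analysis
#'
#' Runs the complete inference block on an analysis-ready cohort table:
#' duration and regularity splits, crossed sleep groups, descriptive
#' statistics of epigenetic age and age-difference at both timepoints,
#' the Time-1 one-way ANOVA of age-difference by sleep group, and three
#' ANCOVA models of the change in age-difference (Time 2 minus Time 1)
#' on the Time-1 age-difference covariate — one with the three crossed
#' groups and two two-group models splitting on duration or regularity
#' alone — with adjusted means at `eval_at` and the pairwise contrasts.
#'
#' @param cohort a cohort data frame (see [read_cohort_csv()]).
#' @param eval_at covariate value for the ANCOVA adjusted means
#'   (default 0: a participant whose ages initially agree).
#' @return A structured list; see sections in the source or the report
#'   JSON written by [run_full()].
#' @export
analyze_cohort <- function(cohort, eval_at = 0) {
  tst <- stats::setNames(cohort$tst, cohort$participant_id)
  sri <- stats::setNames(cohort$sri, cohort$participant_id)
  dur <- classify_duration(tst)
  reg <- classify_regularity(sri)
  grp <- cross_groups(dur, reg$labels)
  d1 <- age_difference(cohort$epi_t1, cohort$chron_t1)
  d2 <- age_difference(cohort$epi_t2, cohort$chron_t2)
  change <- d2 - d1

  grp_stats <- function(lab) {
    lapply(split(seq_along(lab), lab), function(i) {
      list(n = length(i), tst_mean = mean(tst[i]), tst_sd = stats::sd(tst[i]),
           sri_mean = mean(sri[i]), sri_sd = stats::sd(sri[i]))
    })
  }
  anc3 <- ancova_adjusted_means(change, d1, grp, eval_at = eval_at)
  anc_tst <- ancova_adjusted_means(change, d1, dur, eval_at = eval_at)
  anc_sri <- ancova_adjusted_means(change, d1, reg$labels, eval_at = eval_at)

  list(
    groups = list(
      duration = stats::setNames(as.character(dur), names(dur)),
      regularity = stats::setNames(as.character(reg$labels), names(dur)),
      crossed = stats::setNames(as.character(grp), names(dur)),
      sri_median = reg$median,
      by_duration = grp_stats(dur), by_regularity = grp_stats(reg$labels),
      by_crossed = grp_stats(grp)),
    descriptives = list(
      chron_t1 = descriptives(cohort$chron_t1),
      epi_t1 = descriptives(cohort$epi_t1),
      epi_t2 = descriptives(cohort$epi_t2),
      age_diff_t1 = descriptives(d1),
      age_diff_t2 = descriptives(d2),
      r_chron_epi_t1 = pearson_r(cohort$chron_t1, cohort$epi_t1)),
    anova_t1 = list(
      crossed = oneway_anova(d1, grp),
      duration = oneway_anova(d1, dur),
      regularity = oneway_anova(d1, reg$labels)),
    ancova = list(crossed = anc3, duration = anc_tst,
                  regularity = anc_sri),
    contrasts = list(
      shorter_vs_longer = group_contrast(anc_tst, "Shorter", "Longer"),
      less_vs_more = group_contrast(anc_sri, "Less", "More"),
      poor_vs_good = group_contrast(anc3, "Poor", "Good")),
    eval_at = eval_at)
}

strip_classes <- function(x) {
  if (inherits(x, "ancova_fit")) x <- unclass(x)
  if (is.data.frame(x)) return(x)
  if (is.list(x)) return(lapply(x, strip_classes))
  x
}

#' Run configuration for the full pipeline
#'
#' @param diary_csv optional diary file; enables the SRI/TST stage.
#' @param cohort_csv optional analysis-ready cohort file; enables the
#'   statistics stage directly.
#' @param betas_tsv,probes_csv,clock_csv,cellref_tsv optional methylation
#'   inputs; enable the clock stage.
#' @param epoch_min SRI epoch length (minutes).
#' @param sri_mode `"probabilistic"` (default), `"binary"`, or
#'   `"literal"`.
#' @param bmiq,cell_correct clock-stage switches.
#' @param adult_age age-transformation branch point override (used only
#'   when the clock file carries no `(AdultAge)` row).
#' @param eval_at ANCOVA evaluation point.
#' @param out_dir output directory (created if needed).
#' @param seed integer seed recorded in the report (the analysis stages
#'   are deterministic; the seed matters for simulation-backed runs).
#' @return A `run_config` list, paths checked to exist.
#' @export
run_config <- function(diary_csv = NULL, cohort_csv = NULL,
                       betas_tsv = NULL, probes_csv = NULL,
                       clock_csv = NULL, cellref_tsv = NULL,
                       epoch_min = 1L,
                       sri_mode = c("probabilistic", "binary", "literal"),
                       bmiq = FALSE, cell_correct = FALSE, adult_age = 20,
                       eval_at = 0, out_dir = ".", seed = 1L) {
  sri_mode <- match.arg(sri_mode)
  if (!is.finite(eval_at)) stop("eval_at must be finite")
  cfg <- as.list(environment())
  for (p in c("diary_csv", "cohort_csv", "betas_tsv", "probes_csv",
              "clock_csv", "cellref_tsv")) {
    if (!is.null(cfg[[p]]) && !file.exists(cfg[[p]])) {
      stop("input does not exist: ", cfg[[p]])
    }
  }
  cfg
}

run_stage <- function(name, expr) {
  message(sprintf("[somnoclock] stage %s", name))
  tryCatch(force(expr),
           error = function(e) stop("stage '", name, "' failed: ",
                                    conditionMessage(e), call. = FALSE))
}

#' Run the full pipeline
#'
#' Orchestrates diaries -> TST/SRI summaries, betas -> epigenetic ages,
#' and cohort -> inference, writing a versioned JSON report plus CSV
#' tables into the output directory. Every stage logs to stderr with the
#' md5 of its inputs; any stage failure aborts with the stage name while
#' partial outputs written so far are preserved. Human-readable CSV
#' tables are rounded to 2 dp; the JSON report carries full precision.
#'
#' @param config a [run_config()].
#' @return The report list, invisibly; side effect: `report.json` and
#'   stage CSVs in `config$out_dir`.
#' @export
run_full <- function(config) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  inputs <- Filter(Negate(is.null),
                   config[c("diary_csv", "cohort_csv", "betas_tsv",
                            "probes_csv", "clock_csv", "cellref_tsv")])
  for (p in names(inputs)) {
    message(sprintf("[somnoclock] input %s = %s (md5 %s)", p, inputs[[p]],
                    unname(tools::md5sum(inputs[[p]]))))
  }
  report <- list(tool = "somnoclock",
                 version = as.character(utils::packageVersion("somnoclock")),
                 seed = config$seed, eval_at = config$eval_at,
                 sri_mode = config$sri_mode)

  if (!is.null(config$diary_csv)) {
    diary <- run_stage("read-diaries", read_diary_csv(config$diary_csv))
    sri_fun <- if (config$sri_mode == "binary") sri_binary else
      sri_probabilistic
    weighting <- if (config$sri_mode == "literal") "opposing" else
      "probability"
    sris <- run_stage("sri", {
      ids <- unique(diary$participant_id)
      vapply(ids, function(pid) {
        g <- diary_to_grid(diary[diary$participant_id == pid, ],
                           epoch_min = config$epoch_min,
                           weighting = weighting)
        sri_fun(g)$value
      }, numeric(1))
    })
    summ <- run_stage("summaries",
                      summarize_participants(diary, sri = sris))
    utils::write.csv(summ, file.path(config$out_dir, "participants.csv"),
                     row.names = FALSE, quote = FALSE)
    report$participants <- summ
  }

  if (!is.null(config$betas_tsv)) {
    ages <- run_stage("clock", {
      betas <- read_beta_tsv(config$betas_tsv)
      clock <- read_clock_csv(config$clock_csv)
      ann <- if (!is.null(config$probes_csv)) {
        read_probe_annotation(config$probes_csv)
      } else NULL
      cellref <- if (!is.null(config$cellref_tsv)) {
        read_beta_tsv(config$cellref_tsv)
      } else NULL
      clock_chain(betas, clock, annotation = ann, cell_reference = cellref,
                  bmiq = config$bmiq, cell_correct = config$cell_correct)
    })
    age_tab <- data.frame(sample_id = names(ages$ages),
                          epigenetic_age = round(unname(ages$ages), 2))
    utils::write.csv(age_tab, file.path(config$out_dir, "ages.csv"),
                     row.names = FALSE, quote = FALSE)
    report$ages <- stats::setNames(as.numeric(ages$ages), names(ages$ages))
  }

  if (!is.null(config$cohort_csv)) {
    cohort <- run_stage("read-cohort", read_cohort_csv(config$cohort_csv))
    res <- run_stage("stats", analyze_cohort(cohort,
                                             eval_at = config$eval_at))
    report$analysis <- strip_classes(res)
    adj <- res$ancova$crossed$means
    utils::write.csv(
      data.frame(group = adj$group, n = adj$n,
                 adjusted_mean = round(adj$adjusted, 2),
                 ci_lo = round(adj$ci_lo, 2), ci_hi = round(adj$ci_hi, 2)),
      file.path(config$out_dir, "ancova_adjusted_means.csv"),
      row.names = FALSE, quote = FALSE)
  }

  jsonlite::write_json(report, file.path(config$out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       na = "null")
  message("[somnoclock] report written to ",
          file.path(config$out_dir, "report.json"))
  invisible(report)
}
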