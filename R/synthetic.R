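#' Simulation configurations
#'
#' `diary_sim_config()` parameterizes the sleep-diary generator: one
#' diary row per participant-day, with per-day bedtime and time-in-bed
#' drawn from normal distributions, Bernoulli naps with exponential
#' durations, Poisson night awakenings with exponential per-event
#' durations, and independent missing days. Defaults emulate first-year
#' college students tracked over a nine-week (63-day) term: bedtime
#' around 00:30 with 1 h day-to-day jitter, about 8 h in bed.
#'
#' `methyl_sim_config()` parameterizes paired-timepoint methylation-array
#' simulation: clock probes carry a transformed-age signal
#' (`beta = b0 + u * m(age)` with the generating clock satisfying
#' `sum(w * u) = 1`, so scoring with the truth clock at zero noise
#' recovers ages exactly), background probes are cell-type mixtures of
#' reference profiles with Dirichlet-distributed proportions, type II
#' probes can be compressed toward 0.5 to emulate the two-chemistry
#' distributional shift, and each group's Time-2 age drifts by a stated
#' number of years over the interval.
#'
#' @param n_participants,n_days diary panel dimensions (63-day default:
#'   a nine-week observation window).
#' @param bedtime_mean,bedtime_sd bedtime distribution, hours on the
#'   noon-to-noon axis.
#' @param time_in_bed_mean,time_in_bed_sd nightly time in bed, hours.
#' @param nap_prob,nap_min_mean daily nap probability and mean nap
#'   minutes.
#' @param awakening_rate,awakening_min_mean Poisson rate of night
#'   awakenings and mean minutes per awakening.
#' @param missing_prob probability a diary day is missing (must be < 1).
#' @param seed master seed; per-participant streams are derived from it.
#' @return A config list.
#' @export
diary_sim_config <- function(n_participants = 12L, n_days = 63L,
                             bedtime_mean = 24.5, bedtime_sd = 1.0,
                             time_in_bed_mean = 8.0, time_in_bed_sd = 0.75,
                             nap_prob = 0.2, nap_min_mean = 45,
                             awakening_rate = 0.8, awakening_min_mean = 10,
                             missing_prob = 0.05, seed = 1L) {
  stopifnot(n_participants >= 1, n_days >= 1, bedtime_sd >= 0,
            time_in_bed_sd >= 0, nap_prob >= 0, nap_prob <= 1,
            missing_prob >= 0, missing_prob <= 1)
  if (time_in_bed_mean <= 0 || time_in_bed_mean >= 24) {
    stop("infeasible config: time in bed must lie in (0, 24) hours")
  }
  if (missing_prob >= 1) {
    stop("no-data: missing_prob = 1 leaves nothing to simulate")
  }
  as.list(environment())
}

# One RNG stream per participant/sample: a fixed affine hash of the master
# seed and the unit index, reduced mod 2^31 - 1. Stable under reordering.
stream_seed <- function(seed, unit) {
  as.integer((as.numeric(seed) * 100003 + 7919 * as.numeric(unit)) %%
               2147483647)
}

#' Simulate sleep diaries with known truth
#'
#' @param config a [diary_sim_config()].
#' @return List with `diary` (a [sleep_diary()] over all participants)
#'   and `truth` (per-day true sleep minutes plus the nap placement the
#'   diary itself discards, for quantifying what the probabilistic SRI
#'   loses).
#' @export
simulate_diaries <- function(config) {
  rows <- list(); truths <- list()
  for (i in seq_len(config$n_participants)) {
    set.seed(stream_seed(config$seed, i))
    pid <- sprintf("p%02d", i)
    bed <- pmin(pmax(stats::rnorm(config$n_days, config$bedtime_mean,
                                  config$bedtime_sd), 12.01), 35)
    tib <- pmin(pmax(stats::rnorm(config$n_days, config$time_in_bed_mean,
                                  config$time_in_bed_sd), 0.5), 23)
    tib <- pmin(tib, 35.99 - bed)           # keep waketime inside [12, 36)
    nnap <- stats::rbinom(config$n_days, 1L, config$nap_prob)
    napm <- ifelse(nnap > 0,
                   pmin(stats::rexp(config$n_days, 1 / config$nap_min_mean),
                        0.5 * 60 * (24 - tib)), 0)
    nawk <- stats::rpois(config$n_days, config$awakening_rate)
    awkm <- vapply(seq_len(config$n_days), function(d) {
      if (nawk[d] == 0) return(0)
      min(sum(stats::rexp(nawk[d], 1 / config$awakening_min_mean)),
          0.5 * 60 * tib[d])
    }, numeric(1))
    miss <- stats::runif(config$n_days) < config$missing_prob
    # truth keeps the timing the diary discards: nap start (hours into the
    # wake period) and awakening midpoint (hours into the sleep period)
    nap_start <- stats::runif(config$n_days) *
      pmax(24 - tib - napm / 60, 0)
    awk_mid <- stats::runif(config$n_days)
    rows[[i]] <- sleep_diary(pid, seq_len(config$n_days) - 1L, bed,
                             bed + tib, nawk, awkm, nnap, napm, miss)
    truths[[i]] <- data.frame(
      participant_id = pid, day_index = seq_len(config$n_days) - 1L,
      true_sleep_min = ifelse(miss, NA, 60 * tib - awkm + napm),
      nap_start_h = ifelse(nnap > 0 & !miss, nap_start, NA),
      awakening_frac = ifelse(nawk > 0 & !miss, awk_mid, NA),
      stringsAsFactors = FALSE)
  }
  diary <- do.call(rbind, rows)
  class(diary) <- c("sleep_diary", "data.frame")
  list(diary = validate_diary(diary), truth = do.call(rbind, truths))
}

#' @rdname diary_sim_config
#' @param n_samples number of participants (one sample per timepoint
#'   each).
#' @param n_clock_probes,n_background_probes probe counts.
#' @param type2_fraction fraction of probes assigned design type II.
#' @param weight_scale typical magnitude of clock coefficients.
#' @param true_ages_t1 optional numeric vector of Time-1 ages; by default
#'   drawn uniformly on 18-20 years within the generator.
#' @param interval_years elapsed time between the two draws (default 9
#'   weeks).
#' @param groups optional factor of group labels per sample.
#' @param drift named years-of-epigenetic-age drift per group level over
#'   the interval (on top of `interval_years` of ordinary aging).
#' @param n_cell_types,dirichlet_conc cell mixture structure (3-type toy
#'   default keeps deconvolution tests fast; use 6 to mirror blood
#'   references).
#' @param cell_shift sd of cell-type-specific offsets added to clock
#'   probes (0 = no cell confounding of the age signal).
#' @param type2_shift strength of the type II compression toward 0.5
#'   (0 = no distributional shift).
#' @param noise_sd iid Gaussian noise on betas.
#' @param adult_age branch point of the generating clock.
#' @export
methyl_sim_config <- function(n_samples = 12L, n_clock_probes = 30L,
                              n_background_probes = 170L,
                              type2_fraction = 0.5, weight_scale = 0.3,
                              true_ages_t1 = NULL,
                              interval_years = 63 / 365.25,
                              groups = NULL, drift = NULL,
                              n_cell_types = 3L, dirichlet_conc = 10,
                              cell_shift = 0, type2_shift = 0,
                              noise_sd = 0, adult_age = 20, seed = 1L) {
  stopifnot(n_samples >= 2, n_clock_probes >= 1, n_background_probes >= 1,
            noise_sd >= 0, n_cell_types >= 1)
  if (!is.null(drift) && any(!is.finite(drift))) stop("drift must be finite")
  as.list(environment())
}

rdirichlet1 <- function(k, conc) {
  g <- stats::rgamma(k, conc)
  g / sum(g)
}

#' Simulate paired-timepoint methylation arrays
#'
#' @param config a [methyl_sim_config()].
#' @return List with `beta_t1`, `beta_t2` (probes x samples),
#'   `annotation` (design types), `cell_reference` (background-probe
#'   reference profiles), and `truth` (ages at both timepoints, cell
#'   proportions, the generating [clock_model()], group labels, and the
#'   config echo).
#' @export
simulate_methylation <- function(config) {
  set.seed(stream_seed(config$seed, 0))
  np <- config$n_clock_probes; nb <- config$n_background_probes
  ns <- config$n_samples
  probes <- sprintf("cg%06d", seq_len(np + nb))
  cp <- probes[seq_len(np)]; bp <- probes[np + seq_len(nb)]
  samples <- sprintf("s%02d", seq_len(ns))

  w <- sample(c(-1, 1), np, replace = TRUE) *
    stats::runif(np, 0.5, 1.5) * config$weight_scale
  b0 <- stats::runif(np, 0.35, 0.65)
  u <- sign(w) * stats::runif(np, 0.5, 1.5)
  u <- u / sum(w * u)                       # so sum(w * beta) tracks m(age)
  m_max <- max(abs(age_forward(c(10, 40), config$adult_age)))
  margin <- pmin(b0, 1 - b0) - 0.02
  over <- max(abs(u) * m_max / margin)
  if (over > 1) {
    warning("clock weight scale would saturate betas; rescaling")
    u <- u / over
    w <- w * over                           # keeps sum(w * u) = 1
  }
  clock <- clock_model(intercept = -sum(w * b0),
                       weights = stats::setNames(w, cp),
                       adult_age = config$adult_age)

  k <- config$n_cell_types
  cells <- paste0("cell", seq_len(k))
  ref <- matrix(stats::rbeta(nb * k, 2, 2), nb, k,
                dimnames = list(bp, cells))
  clock_cell_shift <- matrix(stats::rnorm(np * k, 0, config$cell_shift),
                             np, k)

  ages1 <- if (is.null(config$true_ages_t1)) {
    stats::runif(ns, 18, 20)
  } else config$true_ages_t1
  if (length(ages1) != ns) stop("true_ages_t1 must have one age per sample")
  groups <- if (is.null(config$groups)) {
    factor(rep("all", ns))
  } else as.factor(config$groups)
  dr <- rep(0, ns)
  if (!is.null(config$drift)) {
    dr <- unname(config$drift[as.character(groups)])
    dr[is.na(dr)] <- 0
  }
  ages2 <- ages1 + config$interval_years + dr

  build <- function(ages, which_t) {
    props <- matrix(NA_real_, ns, k, dimnames = list(samples, cells))
    beta <- matrix(NA_real_, np + nb, ns, dimnames = list(probes, samples))
    for (s in seq_len(ns)) {
      set.seed(stream_seed(config$seed, 1000 * which_t + s))
      props[s, ] <- rdirichlet1(k, config$dirichlet_conc)
      m <- age_forward(ages[s], config$adult_age)
      beta[cp, s] <- b0 + u * m + drop(clock_cell_shift %*% props[s, ])
      beta[bp, s] <- drop(ref %*% props[s, ])
      if (config$noise_sd > 0) {
        beta[, s] <- beta[, s] + stats::rnorm(np + nb, 0, config$noise_sd)
      }
    }
    list(beta = pmin(pmax(beta, 1e-6), 1 - 1e-6), props = props)
  }
  t1 <- build(ages1, 1L); t2 <- build(ages2, 2L)

  set.seed(stream_seed(config$seed, 999999))
  type <- ifelse(stats::runif(np + nb) < config$type2_fraction, "II", "I")
  annotation <- stats::setNames(type, probes)
  distort <- function(beta) {
    if (config$type2_shift <= 0) return(beta)
    cexp <- 1 / (1 + config$type2_shift)
    i2 <- which(annotation[rownames(beta)] == "II")
    beta[i2, ] <- beta[i2, ]^cexp /
      (beta[i2, ]^cexp + (1 - beta[i2, ])^cexp)
    beta
  }
  list(beta_t1 = distort(t1$beta), beta_t2 = distort(t2$beta),
       annotation = annotation, cell_reference = ref,
       truth = list(ages_t1 = stats::setNames(ages1, samples),
                    ages_t2 = stats::setNames(ages2, samples),
                    props_t1 = t1$props, props_t2 = t2$props,
                    clock = clock, groups = stats::setNames(groups, samples),
                    config = config))
}

#' Simulate a 12-participant cohort table
#'
#' End-to-end smoke fixture shaped like the pilot study: 12 participants,
#' six longer and six shorter sleepers, regularity correlated with
#' duration so that crossing the two splits yields 4/4/4 Good/Mixed/Poor
#' groups, paired chronological and epigenetic ages with group-dependent
#' drift over a nine-week interval.
#'
#' @param seed integer seed; the output is deterministic per seed.
#' @param drift named vector of epigenetic-age change (years) by group.
#' @param change_sd sd of the idiosyncratic change component.
#' @return A cohort data frame in the [read_cohort_csv()] layout.
#' @export
make_cohort <- function(seed = 1L,
                        drift = c(Good = -2.5, Mixed = -0.5, Poor = 3),
                        change_sd = 2) {
  set.seed(stream_seed(seed, 42))
  n <- 12L
  longer <- rep(c(TRUE, FALSE), each = 6)
  more <- c(TRUE, TRUE, TRUE, TRUE, FALSE, FALSE,   # 4 of 6 longer regular
            TRUE, TRUE, FALSE, FALSE, FALSE, FALSE) # 2 of 6 shorter
  for (try in 1:100) {
    tst <- ifelse(longer, stats::rnorm(n, 8.04, 0.24),
                  stats::rnorm(n, 5.95, 0.62))
    sri <- ifelse(more, stats::rnorm(n, 81.3, 3.0),
                  stats::rnorm(n, 66.2, 7.9))
    dur_ok <- all((rank(-tst) <= 6) == longer) &&
      !any(duplicated(tst))
    reg_ok <- all((sri > stats::median(sri)) == more) &&
      !any(duplicated(sri))
    if (dur_ok && reg_ok) break
    if (try == 100) stop("could not realize the configured group structure")
  }
  grp <- ifelse(longer & more, "Good",
                ifelse(!longer & !more, "Poor", "Mixed"))
  chron1 <- stats::runif(n, 18.2, 19.8)
  chron2 <- chron1 + 63 / 365.25
  epi1 <- chron1 + stats::rnorm(n, 2.07, 3.3)
  change <- unname(drift[grp]) + stats::rnorm(n, 0, change_sd)
  epi2 <- epi1 + 63 / 365.25 + change
  data.frame(participant_id = sprintf("p%02d", seq_len(n)),
             chron_t1 = round(chron1, 2), chron_t2 = round(chron2, 2),
             epi_t1 = round(epi1, 2), epi_t2 = round(epi2, 2),
             tst = round(tst, 2), sri = round(sri, 2),
             stringsAsFactors = FALSE)
}
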