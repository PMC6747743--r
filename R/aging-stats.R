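#' Age-difference (epigenetic age acceleration)
#'
#' Epigenetic minus chronological age; a positive value means the sample
#' looks epigenetically older than its chronology.
#'
#' @param epigenetic,chronological ages in years.
#' @return Years of age-difference.
#' @export
age_difference <- function(epigenetic, chronological) {
  stopifnot(is.finite(epigenetic), is.finite(chronological))
  epigenetic - chronological
}

check_boundary_tie <- function(x, what) {
  n <- length(x)
  s <- sort(x)
  if (s[n / 2] == s[n / 2 + 1]) {
    stop("unsplittable-tie: ", what, " values tie across the split boundary")
  }
}

#' Classify sleep duration (Longer vs Shorter sleepers)
#'
#' Splits participants at the TST median: the top half are Longer
#' Sleepers, the bottom half Shorter Sleepers. An even count is required,
#' and a tie straddling the boundary is an error rather than silently
#' broken — the split must be reproducible.
#'
#' @param tst named numeric vector of average TST (hours) per participant.
#' @return Factor with levels `Longer`, `Shorter`, named as `tst`.
#' @export
classify_duration <- function(tst) {
  n <- length(tst)
  if (n < 2 || n %% 2 != 0) stop("duration split needs an even count")
  check_boundary_tie(tst, "TST")
  lab <- ifelse(rank(-tst, ties.method = "min") <= n / 2, "Longer", "Shorter")
  stats::setNames(factor(lab, levels = c("Longer", "Shorter")), names(tst))
}

#' Classify sleep regularity (More vs Less regulated)
#'
#' Median split on SRI (even n: midpoint of the two central order
#' statistics). Values strictly above the median are More Regulated,
#' strictly below are Less Regulated; a tie at the boundary is an error.
#'
#' @param sri named numeric vector of SRI scores.
#' @return List with `labels` (factor, levels `More`, `Less`) and
#'   `median`.
#' @export
classify_regularity <- function(sri) {
  n <- length(sri)
  if (n < 2) stop("regularity split needs at least two participants")
  if (n %% 2 == 0) check_boundary_tie(sri, "SRI")
  med <- stats::median(sri)
  if (any(sri == med) && n %% 2 == 0) {
    stop("unsplittable-tie: SRI equal to the split median")
  }
  lab <- ifelse(sri > med, "More", "Less")
  list(labels = stats::setNames(factor(lab, levels = c("More", "Less")),
                                names(sri)),
       median = med)
}

#' Cross duration and regularity splits into sleep groups
#'
#' Good Sleep = Longer and More Regulated; Poor Sleep = Shorter and Less
#' Regulated; Mixed Sleep = exactly one of the two.
#'
#' @param duration factor from [classify_duration()].
#' @param regularity factor from [classify_regularity()]`$labels`.
#' @return Factor with levels `Good`, `Mixed`, `Poor`, named by
#'   participant.
#' @export
cross_groups <- function(duration, regularity) {
  if (!identical(names(duration), names(regularity))) {
    stop("duration and regularity labels cover different participants")
  }
  g <- ifelse(duration == "Longer" & regularity == "More", "Good",
              ifelse(duration == "Shorter" & regularity == "Less",
                     "Poor", "Mixed"))
  stats::setNames(factor(g, levels = c("Good", "Mixed", "Poor")),
                  names(duration))
}

#' Descriptive statistics
#'
#' @param x numeric vector, `n >= 1` (`sd` needs `n >= 2`).
#' @return List with `n`, `mean`, `sd` (denominator n-1), `min`, `max`,
#'   `median`.
#' @export
descriptives <- function(x) {
  if (length(x) < 1) stop("descriptives of an empty vector")
  list(n = length(x), mean = mean(x),
       sd = if (length(x) >= 2) stats::sd(x) else NA_real_,
       min = min(x), max = max(x), median = stats::median(x))
}

#' Pearson product-moment correlation
#'
#' @param x,y numeric vectors, `n >= 3`, each with nonzero variance.
#' @return Correlation in `[-1, 1]`.
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3) {
    stop("pearson_r needs paired vectors of length >= 3")
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("zero variance in x or y")
  }
  stats::cor(x, y)
}

#' One-way analysis of variance
#'
#' Between/within decomposition of `y` by `groups`, with the p-value from
#' the F distribution. Zero within-group variance with differing means is
#' reported as infinite F.
#'
#' @param y numeric response.
#' @param groups factor (or coercible) of group labels.
#' @return List with `f`, `df` (length-2), `p`, and the sums of squares
#'   `ss_between`, `ss_within`.
#' @export
oneway_anova <- function(y, groups) {
  groups <- droplevels(as.factor(groups))
  k <- nlevels(groups)
  n <- length(y)
  if (k < 2) stop("need at least two groups")
  if (any(table(groups) < 1) || n <= k) {
    stop("each group needs data and total n must exceed the group count")
  }
  tab <- stats::anova(stats::lm(y ~ groups))
  f <- tab$`F value`[1]
  if (tab$`Sum Sq`[2] <= 1e-12 * (tab$`Sum Sq`[1] + tab$`Sum Sq`[2]) &&
      tab$`Sum Sq`[1] > 0) {
    f <- Inf
  }
  list(f = f, df = c(tab$Df[1], tab$Df[2]),
       p = if (is.infinite(f)) 0 else tab$`Pr(>F)`[1],
       ss_between = tab$`Sum Sq`[1], ss_within = tab$`Sum Sq`[2])
}
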