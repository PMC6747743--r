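---
title: "Methods: sleep regularity, epigenetic clocks, and the cohort inference in somnoclock"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: sleep regularity, epigenetic clocks, and the cohort inference in somnoclock}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(somnoclock)
```

somnoclock implements a prospective sleep/epigenetic-aging analysis as a
tested pipeline: daily sleep diaries become total-sleep-time (TST) and
Sleep Regularity Index (SRI) summaries; methylation beta matrices become
epigenetic ages via BMIQ normalization, cell-composition correction, and a
coefficient-driven clock; and the cohort table becomes group comparisons
via ANOVA and ANCOVA with adjusted means. A synthetic-data module
generates diaries and paired-timepoint arrays with known ground truth so
that every stage is verifiable offline. This vignette records the models,
the parameter choices, and the design decisions that were genuinely open.

## Sleep diaries and total sleep time

Diaries are per-day records of bedtime, rise time, and the *totals* (not
timings) of naps and night awakenings. Clock times live on a noon-to-noon
axis — hours after midnight of the diary date, in $[12, 36)$ — so a
bedtime of 25.85 is 01:51 the next calendar day and every night's sleep
period sits inside a single diary day, with no midnight wraparound
arithmetic anywhere in the code. Published cohort tables often mix
conventions (a bedtime printed as 24.77 alongside one printed as 01.85);
in somnoclock that is display-level only (`mean_clock_time()`).

Daily TST is defined as

$$\mathrm{TST} = (\text{waketime} - \text{bedtime}) -
  \text{awake}_{\min}/60 + \text{nap}_{\min}/60,$$

clamped at zero. Diary instruments rarely pin this formula down; we chose
the conventional reading — total sleep excludes wake after sleep onset and
includes naps — and treat it as a documented package definition. In the
packaged pilot cohort the printed per-participant TST values are
consistent with this formula (TST below time-in-bed for most rows), but
the instrument's own definition is not recoverable from the publication,
so the formula is a package choice, not a reproduction. `average_tst()`
averages over non-missing days only; missing days are never imputed.

Validation is strict by default; a permissive mode clamps awakening/nap
minutes that exceed their containing period and warns, for field data
with entry errors.

## The Sleep Regularity Index and its probabilistic variant

The standard SRI compares sleep/wake state at epochs 24 h apart:

$$\mathrm{SRI} = -100 + \frac{200}{N} \sum_{\text{pairs}}
  \mathbb{1}[s_{d,j} = s_{d+1,j}],$$

so identical days score 100 and unrelated days score near 0. Diaries,
however, say *how much* of the night was spent awake and *how much* of
the day was napped, but not when. `diary_to_grid()` therefore fills each
night epoch with the probability
$p = 1 - \text{awake}_{\min} / (60\,\text{sleep-period h})$ and each wake
epoch with $p = \text{nap}_{\min} / (60\,\text{wake-period h})$ (epochs
straddling a boundary get the duration-weighted blend), and
`sri_probabilistic()` scores pairwise agreement as

$$a = p_1 p_2 + (1 - p_1)(1 - p_2),$$

the probability that two independent states drawn with those
probabilities coincide. On a strictly binary grid this reduces exactly to
the standard SRI (the suite checks all 64 two-day three-epoch binary
grids against a brute-force pair enumerator), a constant grid at
$p = 0.5$ scores 0, and a perfectly regular schedule with night
$p = 0.9$ / day $p = 0.1$ scores exactly
$-100 + 200(0.81 + 0.01) = 64$.

The phrase "index values multiplied by the proportion of the period spent
in the opposing state" admits a second, literal reading in which the
epoch value *is* the opposing-state proportion. We implement it
(`diary_to_grid(weighting = "opposing")`) but do not default to it: under
the pairwise agreement statistic it discards the sleep/wake contrast
itself — an unbroken sleeper's nights and days both carry values near
zero and the score saturates regardless of schedule alignment — whereas
the probabilistic reading preserves the standard SRI as its binary
special case and respects the published $[-100, 100]$ interpretation.
Raw diaries are not published, so the cohort's printed SRI values cannot
discriminate between the readings.

Defaults: 1-minute epochs (configurable; any divisor of 1440), and pairs
with a missing member are dropped from numerator and denominator alike,
so missing days shrink the pair set without biasing the mean.

## The epigenetic clock chain

The pipeline deliberately starts at beta matrices (methylation fractions
in $[0,1]$, probes × samples). IDAT decoding and raw-intensity quantile
normalization are platform plumbing handled by existing array software;
the analysis-specific chain is BMIQ → cell correction → clock scoring.

**BMIQ.** The two Infinium probe chemistries report different beta
distributions (type II compressed toward 0.5). `fit_beta_mixture()` fits
a three-state (unmethylated / hemimethylated / methylated) beta mixture
by EM. The M-step improves each state's shape parameters by bounded
L-BFGS-B ascent from the current values — a generalized EM step, so the
log-likelihood is provably non-decreasing — with shapes bounded in
$[0.1, 10^4]$, values clamped to $[10^{-6}, 1-10^{-6}]$, relative
log-likelihood tolerance $10^{-6}$, and at most 500 iterations.
Initialization is deterministic (empirical terciles), so fits are
bit-reproducible without a seed. `bmiq_normalize()` assigns each type II
probe to its maximum-responsibility state, maps U- and M-state probes
onto the type I state distributions by quantile transformation (upper
tail for M, so the methylated extreme is handled symmetrically), and
linearly dilates the hemimethylated block into the gap between the
transformed U and M regions. Type I probes are never modified, and all
three maps are monotone, so within-state ranks are preserved. When a
sample carries only one design type the default is pass-through rather
than an error.

**Cell composition.** `estimate_cell_proportions()` projects each sample
onto flow-sorted reference profiles by constrained least squares
($w \ge 0$, $\sum w \le 1$, then renormalized to 1), solved with
`quadprog`. The inequality constraint tolerates references that do not
span every cell type present. `celltype_correct()` then removes the
composition signal per probe by OLS residualization against the
proportions, re-centered at the cohort-mean composition so corrected
values stay on the beta scale. The residualization operator is a package
choice — published clock pipelines say "corrected for cell type" without
an equation — and the cohort-level acceptance surface does not depend on
it because the packaged fixture's ages are taken as given.

**Clock scoring.** A clock is an intercept plus sparse probe weights plus
an `adult_age` constant, read from CSV at run time (never hard-coded), so
any published coefficient set in that layout can be dropped in. Scoring
is `age_inverse(intercept + sum(w * beta))` with the piecewise
log/linear transformation

$$m(a) = \begin{cases}
  \log(a+1) - \log(a_{\mathrm{adult}}+1) & a \le a_{\mathrm{adult}}\\
  (a - a_{\mathrm{adult}})/(a_{\mathrm{adult}}+1) & a > a_{\mathrm{adult}},
\end{cases}$$

default branch point 20 years; `age_inverse()` is its exact inverse
(round-trip checked to $10^{-9}$ over 1000 ages).

## Groups, ANOVA, and ANCOVA

Age-difference is epigenetic minus chronological age. Participants are
split at the TST median (Longer vs Shorter sleepers; in the pilot design
this mirrors the upper/lower-quintile selection from the parent cohort)
and at the SRI median (More vs Less Regulated); crossing the splits
gives Good (both favorable), Poor (both unfavorable), and Mixed sleep
groups. Boundary ties are an error, never silently broken: the split
must be reproducible from the printed values.

Baseline differences are tested with one-way ANOVA of Time-1
age-difference. Change over the interval is tested with a common-slope
ANCOVA: change in age-difference ($T_2 - T_1$) on the Time-1
age-difference covariate plus group indicators. Adjusted means are
reported at a stated covariate value,

$$\hat\mu_g(x_0) = \bar y_g + b\,(x_0 - \bar x_g), \qquad
  \mathrm{SE} = \sqrt{\mathrm{MSE}\left(\tfrac{1}{n_g} +
  \tfrac{(\bar x_g - x_0)^2}{S_{xx,w}}\right)},$$

with t intervals on $n - k - 1$ degrees of freedom, and contrasts
$(\bar y_1 - \bar y_2) - b(\bar x_1 - \bar x_2)$, which are independent
of $x_0$. The default evaluation point is $x_0 = 0$ — the expected
change for a participant whose epigenetic and chronological ages
initially agreed — rather than the covariate grand mean: recomputing
from the packaged tables reproduces every published adjusted mean and
all published CI bounds to within 0.06 (the slack implied by 2-dp
rounding of the inputs) only under this convention. A flag overrides it.
Fitting the Time-2 *level* with the same covariate is an equivalent
model (same SSE and F, slope shifted by exactly +1, identical adjusted
means at $x_0 = 0$), which the suite asserts.

The underlying OLS fits use `stats::lm`; the adjusted-mean, SE, and
contrast algebra above is the package's own and is cross-checked in the
test suite against both a normal-equations solver written independently
of the package and `emmeans`. p-values are two-sided from the F
distribution; no multiplicity correction is applied, matching the
pilot-scale analysis the package reproduces.

Two recomputation caveats are part of the package's account of the
packaged cohort. First, the published ANCOVA F statistics (4.97, 4.72,
10.99) are not consistent with the common-slope model that reproduces
every published adjusted mean and CI bound; the suite pins our
recomputed values (4.30 on df 2,8; 2.86 and 6.55 on df 1,9) against a
frozen independent recomputation instead. Second, the published Time-2
epigenetic-age range (16.03–25.93) contradicts the published
per-participant values, whose minimum is 14.61 — while the published
Time-2 mean and SD (20.12 [3.16]) reproduce only when 14.61 is included.
The recomputed extremes are asserted and the inconsistent printed
minimum is not reported as a result.

## The synthetic-data generators

`simulate_diaries()` draws per-day bedtime and time-in-bed from normal
distributions, Bernoulli naps with exponential durations, Poisson
awakenings with exponential per-event durations, and independent missing
days. Defaults emulate first-year college students over a nine-week
(63-day) term: bedtime 00:30 ± 1 h, 8 ± 0.75 h in bed, 20% nap days
averaging 45 min, 0.8 awakenings/night averaging 10 min each, 5% missing
days — values chosen once as field-realistic for young-adult diary
cohorts. The truth table retains the nap/awakening *timing* that the
diary format discards, so tests can quantify exactly the information the
probabilistic SRI loses.

`simulate_methylation()` builds clock probes as
$\beta_p = b_{0p} + u_p\, m(\text{age})$ with the generating clock
satisfying $\sum_p w_p u_p = 1$ and intercept $-\sum_p w_p b_{0p}$, so
scoring with the truth clock at zero noise recovers ages to machine
precision — the anchor for all recovery tests. Background probes are
Dirichlet-weighted mixtures of per-cell-type reference profiles (3 cell
types by default to keep deconvolution tests fast; 6 mirrors blood
references); optional switches add cell-composition shifts on clock
probes, a type II compression toward 0.5 (so BMIQ has real work to do),
iid beta noise, and per-group epigenetic-age drift at Time 2. A
saturation guard rescales coefficient structure (with a warning) if the
requested weight scale would push betas out of $[0,1]$.

Reproducibility uses one RNG stream per participant/sample, seeded by a
fixed affine hash of the master seed and the unit index
(`(seed * 100003 + 7919 * unit) mod (2^31 - 1)`), so outputs are
bit-identical per seed and stable when units are added or reordered.

What the generators deliberately do not emulate: realistic 450K probe
manifests, batch/chip effects, detection-p QC, or correlated missingness
in diaries. Passing tests therefore demonstrate correctness of the
algorithms under the stated generative assumptions, not robustness to
every artifact of real array or diary data.

`make_cohort()` produces a 12-participant, two-timepoint cohort table
shaped like the pilot study (six longer / six shorter sleepers,
regularity correlated with duration so the crossed groups come out
4/4/4, group-dependent drift), by rejection sampling until the median
splits reproduce the intended classes — deterministic per seed.

## Problem sizes and runtime choices

The test suite runs on one CPU in about a minute: mixture fits use
2 000–5 000 values, deconvolution toys 5–400 probes, and the
drift-recovery study 200 replicate cohorts of 12 samples × 30 probes
(contrast unbiased within 0.3 years; 95% CI coverage inside
[0.90, 0.99]). These sizes were chosen so that every property is
exercised at a scale where its failure modes are visible; the algorithms
themselves are size-agnostic.

The pipeline (`run_full()`) is deterministic and completes in seconds,
so no stage caching is implemented; re-running with identical inputs
reproduces the report byte for byte, which the suite asserts directly.
Human-readable tables are rounded to 2 dp, matching the conventional
presentation; the JSON report keeps full precision.

## Known limitations

The TST formula and the probabilistic-SRI reading are documented choices
where the source instrument is ambiguous; the cell-type-correction
operator is one of several defensible residualizations; GrimAge columns
ship in the fixture for completeness but no GrimAge scorer exists
(coefficients are not public); and the 12-participant fixture supports
exact reproduction, not new inference — the ANCOVA machinery is general,
but pilot-scale group sizes of four carry the wide intervals shown.
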