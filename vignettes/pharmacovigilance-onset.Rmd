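---
title: "Signal detection and time-to-onset modelling for spontaneous adverse-event reports"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Signal detection and time-to-onset modelling for spontaneous adverse-event reports}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pvonset)
```

## The data and the question

Spontaneous reporting systems (SRS) such as Japan's JADER or the FDA's
FAERS collect voluntary reports of suspected adverse drug reactions.
They contain only reported cases — there is no exposure denominator and
no unexposed cohort — so classical risk estimation is impossible.
What can be done, and what this package implements, is:

1. **Disproportionality analysis**: is an event reported more often
   *with* a drug than the rest of the database would predict?
2. **Time-to-onset analysis**: once the association is flagged, how
   long after the start of administration does the event tend to
   appear, and does its hazard rise or fall with time?
3. **Outcome profiling**: how often do affected patients recover?

The motivating application is chemotherapy-induced peripheral
neuropathy (CIPN), identified by a single MedDRA preferred term
(PT 10029331) across reports whose *suspected* drugs are antineoplastic
and immunomodulating agents, but every component is generic over the
PT list and drug vocabulary supplied by the user.

## Data model

The four-table JADER layout is mirrored directly: `demo` (one row per
report), `drug` (prescription records with role codes: suspected,
concomitant, interacting), `reac` (adverse events with onset dates and
outcomes) and `hist` (primary disease, read and validated but not used
by any analysis). All tables join on `case_id`; the number of `demo`
rows is the report denominator used everywhere downstream.

Dates are digit strings at three precisions (`YYYYMMDD`, `YYYYMM`,
`YYYY`). Partial dates are first-class values: they are carried through
assembly, never promoted, and excluded — with explicit counts — exactly
where the analysis needs complete dates. Role and outcome labels are
stored as canonical English tokens; a YAML mapping file translates
source-language labels at read time, so no Japanese strings are
hard-coded.

## Reporting odds ratio

For a drug (or ATC class) \(D\) and event \(E\) the 2x2 table over all
reports is

|            | event \(E\) | no event |
|------------|-------------|----------|
| drug \(D\) | \(a\)       | \(b\)    |
| no drug    | \(c\)       | \(d\)    |

and the reporting odds ratio is \(ROR = (a d)/(b c)\) with the Woolf
(logit) interval
\(\exp\{\log ROR \pm z_{0.975}\sqrt{1/a + 1/b + 1/c + 1/d}\}\).
A **signal** requires \(ROR > 1\), a CI lower bound \(> 1\), and at
least two case reports. Exposure is counted at report level: a report
listing two member drugs of a class contributes once to the class
cell, keeping the denominator a report count.

Design choices worth stating:

* The Woolf interval was chosen because it is the standard SRS formula;
  it reproduces published one-decimal RORs and CIs from marginal counts
  in the package's reference tests.
* Tables with `a < 2` or a zero in `b`, `c`, `d` are reported as
  non-evaluable rather than corrected. A Haldane–Anscombe 0.5
  correction exists behind `haldane = TRUE` and is clearly non-default.
* Reported values are rounded half-up to one decimal at presentation
  only; all internal arithmetic is full precision.
* `run_signal_screen()` recomputes both denominators from the analysis
  set rather than trusting configuration, so they cannot drift.

## Time-to-onset

The latency for a (report, drug) pair is the day difference between
the earliest *complete* start date of that drug and the first
*complete* onset date of the focal event in the same report. Records
are excluded, and the exclusions counted, when

* either date is incomplete (`n_excluded_incomplete`),
* the latency is negative (`n_excluded_negative`), or
* it exceeds the 365-day analysis window (`n_excluded_window`).

Duplicate prescription rows are collapsed at assembly; the collapsed
row count travels with the latency set (`n_excluded_duplicate`). The
365-day window *excludes* longer latencies rather than censoring them;
since every retained observation is an event, censoring machinery
would only matter for the window rule, and exclusion matches how such
analysis windows are conventionally applied to SRS latencies.

Quantiles use the \((n+1)p\) convention with linear interpolation
(R's type 6), matching the behaviour of the commercial statistics
suites typically used for these tables; the convention is a function
argument because it is not universal.

### Weibull fit and hazard classification

Latencies are fitted by maximum likelihood to the Weibull density
\(f(t) = (\beta/\alpha)(t/\alpha)^{\beta-1} e^{-(t/\alpha)^\beta}\),
optimised over \((\log\alpha, \log\beta)\) (BFGS, moment-style
initialisation from the coefficient of variation, with a small
multi-start fallback). Confidence intervals are Wald intervals on the
log parameters using the observed information, exponentiated back —
this respects positivity and cannot produce a negative lower bound.
The shape parameter indexes the hazard:

* upper CI limit of \(\beta\) below 1 → **initial failure** (hazard
  decreases; onsets cluster early),
* lower limit above 1 → **wear-out failure** (hazard increases),
* otherwise → **random failure** (constant hazard). Both inequalities
  are strict, so a limit exactly at 1 is random failure.

Numerical details: zero-day latencies make the log-density at 0
undefined for \(\beta < 1\), so they enter the fit as 0.5 days (the
count is reported as `n_zero_adjusted`) while medians and quartiles
keep the true zeros. Fits are refused below 10 retained latencies —
the scale of class-level analyses worth reporting — rather than
returning unstable estimates.

### Two-arm comparison

`compare_onset_profiles()` contrasts two exposure groups (the
motivating case: solvent-based vs albumin-bound paclitaxel) with
Kaplan–Meier curves and the Mantel–Cox log-rank test (hypergeometric
variance, ties pooled). With no censoring the product-limit estimate
equals one minus the empirical CDF, which is asserted as an identity
in the tests. Arms below 10 retained latencies produce a warning, not
a refusal: the comparison is descriptive.

## Outcomes

Each case record carries the outcome of its first-listed focal-event
reaction (outcome is tied to the event, not to the report's worst
outcome). Outcomes `unknown` or blank leave the denominator and are
counted separately; the informative categories are death, with
sequelae, not recovered (together "unfavourable") and improved,
recovered ("favourable"). The two fractions are computed from the same
integer denominator, so they sum to one exactly before any rounding.
Exclusion of unknowns happens per drug/class, which reproduces the
published per-arm fractions used as reference values in the tests.
`mosaic_data()` emits column widths proportional to informative
denominators and per-column category proportions for mosaic plotting.

## The synthetic-report generator

Because no SRS extract ships with the package, `generate_dataset()`
creates datasets whose statistical structure matches what the analyses
assume:

* Exposures are independent Bernoulli draws per drug; the focal event
  occurs with odds equal to the background odds times the
  `event_odds_multiplier` of every exposed drug. Parameterising the
  association on the *odds* scale makes the configured multiplier the
  exact estimand of the ROR — `expected_contingency()` returns the
  closed-form expected cells, and in a single-drug configuration their
  odds ratio equals the multiplier exactly. This makes calibration
  tests self-validating.
* Exposed-and-case reports receive an onset equal to the start date
  plus a Weibull latency rounded to whole days (day 0 is emitted as
  such; the fitting stage owns the zero-handling rule). When a case
  report lists several exposed drugs, the latency law of the
  first-listed drug in the configuration is used.
* Start dates are uniform over a configurable calendar year, giving
  realistic date arithmetic without affecting any statistic.
* Dates degrade to year-month with `missing_date_prob`; drug rows are
  cloned under a new `drug_seq` with `duplicate_prescription_prob`;
  outcomes draw from a per-drug six-category mixture.
* A fixed seed reproduces the dataset byte for byte, and the caller's
  RNG stream is left untouched.

The generator emulates report-level co-occurrence structure, not
reporting dynamics: there is no reporting delay, no correlated
co-prescription, no drug–drug interaction, one focal event per
configuration, and non-focal reactions are a single filler term.
Passing tests therefore demonstrate correctness of the estimators
under the assumed generative model — not robustness to the biases of
real spontaneous-report data (under-reporting, confounding by
indication, duplicate case submissions across reports), which no
simulation of this kind can establish.

## Validation strategy and problem sizes

The test suite checks each estimator against an independent route:

* ROR and Woolf CI against an independently coded odds-ratio routine
  on 1,000 random tables (agreement to 1e-10 on the log scale), plus
  published one-decimal table rows recomputed from marginal counts.
* Weibull fits against parameter recovery (mean relative bias below 5%
  over 100 seeds at n = 1,000 draws from Weibull(scale 50, shape 0.8)),
  a likelihood-dominance grid around each optimum, scale equivariance,
  and `fitdistrplus` as an external cross-check.
* The signal rule against 200 null-generator replicates (30,000
  reports each; the one-sided rule on a 95% interval should fire in at
  most ~2.5%, tested against a 5% ceiling with Monte-Carlo margin).
* The log-rank test against an exhaustive 12-choose-6 permutation
  oracle on a fixed small example and against null p-value uniformity
  over 1,000 replicates.
* Kaplan–Meier curves against the 1 − ECDF identity.

These sizes were chosen as the smallest at which the Monte-Carlo
margins above are comfortably discriminating.

## Limitations

* The ROR is a signal-strength index, not a risk estimate; nothing in
  the package adjusts for covariates, multiplicity, or confounding by
  co-prescription.
* The exact quantile and Weibull-CI algorithms behind published
  reference tables are not stated by their sources; published scale
  and shape values are therefore treated as qualitative references,
  and only quantities fully determined by printed counts are asserted
  numerically.
* Within-report ordering of several equal onset dates for the same
  preferred term is undefined in the source schema; the package
  resolves ties by taking the minimum onset date and, for outcomes,
  the first-listed reaction row.
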