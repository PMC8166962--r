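# pvonset

Disproportionality and time-to-onset analysis of spontaneous
adverse-event reports.

Spontaneous reporting systems (SRS) such as JADER or FAERS collect
voluntary reports of suspected adverse drug reactions. They have no
exposure denominator, so drug safety questions are asked through
within-database statistics. `pvonset` implements the standard analysis
chain for one adverse event of interest — the motivating case is
chemotherapy-induced peripheral neuropathy (MedDRA PT 10029331) across
antineoplastic agents — on top of the four-table JADER schema (`demo`,
`drug`, `reac`, `hist`):

* **Signal detection** via the reporting odds ratio on the 2x2 table of
  drug exposure by event reporting, `ROR = (a·d)/(b·c)`, with the Woolf
  95% interval `exp(ln ROR ± 1.96·√(1/a + 1/b + 1/c + 1/d))`; a signal
  requires ROR > 1, CI lower bound > 1 and at least two cases.
* **Time-to-onset**: per-report latency from the earliest complete
  administration start date to the first complete event onset (365-day
  window, negative and incomplete pairs excluded with accounting);
  median/IQR summaries and maximum-likelihood Weibull fits whose shape
  parameter β classifies the hazard — CI entirely below 1: initial
  failure (early-onset clustering), spanning 1: random failure, above
  1: wear-out failure.
* **Two-arm onset comparison** (e.g. solvent-based vs albumin-bound
  paclitaxel) by Kaplan–Meier curves and the log-rank test.
* **Outcome profiling**: the six SRS outcome categories per drug/class,
  combined favourable/unfavourable fractions, mosaic-plot geometry.
* **A calibrated synthetic-report generator** with closed-form expected
  contingency cells, so every estimator can be validated against a
  known generative truth — the configured odds multiplier *is* the ROR
  estimand.

## Worked example

Simulate a 30,000-report database with three associated drugs and run
the full pipeline:

```r
library(pvonset)

sim <- sim_config(30000, background_event_prob = 0.003,
  drugs = list(
    drug_spec("oxaliplatin",    "L01XA03", 0.014, 26, latency_alpha_days = 51, latency_beta = 0.95),
    drug_spec("sb-paclitaxel",  "L01CD01", 0.010, 14, latency_alpha_days = 56, latency_beta = 0.78),
    drug_spec("nab-paclitaxel", "L01CD01", 0.005,  6, latency_alpha_days = 13, latency_beta = 0.74)),
  missing_date_prob = 0.05, duplicate_prescription_prob = 0.05, seed = 31)

cfg <- run_config(pt_codes = 10029331,
                  targets = c("oxaliplatin", "sb-paclitaxel", "nab-paclitaxel"),
                  sim = sim, class_level = 5,
                  compare = c("sb-paclitaxel", "nab-paclitaxel"),
                  seed = 31, out_dir = "run1")
bundle <- run_full_analysis(cfg)
cat(render_report(bundle))
```

```
Spontaneous-report analysis run (seed 31)
Reports: 30000 | focal-event cases: 138

Signals (ROR > 1, CI lower bound > 1, >= 2 cases):
  nab-paclitaxel [L01CD01]: ROR 5.1 (1.9-13.9), 4 cases
  sb-paclitaxel [L01CD01]: ROR 10.8 (6.0-19.3), 13 cases
  oxaliplatin [L01XA03]: ROR 23.9 (15.9-35.8), 33 cases

Time-to-onset (Weibull):
  oxaliplatin: median 32.0 d (IQR 6.0-48.0), alpha 37.2, beta 0.95 (0.70-1.28) -> random_failure
  sb-paclitaxel: median 57.5 d (IQR 13.5-146.8), alpha 79.7, beta 0.91 (0.55-1.49) -> random_failure

Onset comparison: sb-paclitaxel vs nab-paclitaxel: log-rank p = 0.001023 (significant at 0.05)

Outcomes (unfavourable = death + with sequelae + not recovered):
  oxaliplatin: unfavourable 33.3% (10/30), 3 unknown/blank excluded
  sb-paclitaxel: unfavourable 38.5% (5/13), 0 unknown/blank excluded
  nab-paclitaxel: unfavourable 25.0% (1/4), 0 unknown/blank excluded
```

Each estimated ROR sits near its configured multiplier (26, 14, 6);
the albumin-bound arm's configured 13-day latency scale versus 56 days
for the solvent-based arm shows up as a significantly faster onset;
and every reported number is also written as a delimited stage file
(`signals.csv`, `time_to_onset.csv`, `km_curves.csv`, `logrank.csv`,
`outcomes.csv`, `mosaic.csv`) plus a structured `run_log.json` in
`out_dir`. A thin command-line front end over the same functions lives
at `inst/cli/pvonset-cli.R` (`simulate` and `run-all` subcommands).

To analyse a real extract instead, pass `paths = list(demo=, drug=,
reac=, hist=)` and a product-name→ATC vocabulary
(`read_vocabulary()`), plus a YAML code map translating source-language
role/outcome labels (`read_code_map()`).

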