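---
title: "Disproportionality analysis of spontaneous reports: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Disproportionality analysis of spontaneous reports: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pvsignal)
```

## The problem

Spontaneous-report databases such as FAERS collect voluntary post-marketing
submissions, each describing one patient, a set of suspected drug exposures
and a set of adverse events coded as MedDRA preferred terms. Because there is
no denominator of drug users, absolute risks cannot be estimated; what can be
estimated is *disproportionality*: whether a drug–event pair is co-reported
more often than the database background predicts. `pvsignal` implements the
classical reporting-odds-ratio (ROR) approach with the all-other-reports
comparator, the three-part signal rule, and the stratified contrasts used to
ask whether an association differs by sex.

The unit of analysis is the report. A report is "exposed" exactly when its
drug set contains the queried name (exact, case-insensitive,
whitespace-trimmed match — no ingredient mapping or fuzzy matching, since
queries target a single normalized name) and is a "case" exactly when its
event set contains the queried preferred term. No case-version deduplication
is attempted; counts are taken as the database returns them.

## Model and estimators

Writing the 2×2 cells as a (drug and event), b (event only), c (drug only)
and d (neither), with N = a+b+c+d:

* **ROR** = (a·d)/(b·c). On the log scale its large-sample standard error is
  √(1/a + 1/b + 1/c + 1/d) (Woolf), giving the interval
  exp(ln ROR ± z·SE).
* **Multiplier z.** The package default is z = 1.96, the conventional
  two-sided 95% multiplier used by the standard pharmacovigilance tools
  (OpenVigil, SAS-style reporting). This is deliberate: published ROR
  intervals are printed from that convention, and on the packaged
  hydroxychloroquine–pemphigus table the 1.96 multiplier reproduces all
  printed digits (upper bound 306.1475 → 306.148), whereas the exact
  quantile 1.959964 would give 306.14705 → 306.147. The difference never
  exceeds the third decimal; `z` is an explicit argument for users who
  prefer the exact quantile.
* **Zero cells.** When any cell is zero the ROR or its variance is
  undefined; the package then adds 0.5 to *all four* cells
  (Haldane–Anscombe) and flags the result. All-positive tables — including
  every published table handled here — are never modified. With two or more
  empty margins the estimate is refused outright.
* **Yates-corrected χ²** = N·(max(0, |ad − bc| − N/2))² /
  ((a+b)(c+d)(a+c)(b+d)). The correction floors at zero, so perfectly
  independent tables score exactly 0. A zero margin makes the statistic
  undefined (error), not zero.
* **Signal rule.** `signal = (lbROR > 1) & (χ² > 4) & (n > 3)` with n = a.
  All three inequalities are strict: a pair sitting exactly on a threshold
  is not a signal. The rule is a hypothesis-generating flag, not a causal
  claim.
* **Jeffreys rates.** Reporting and exposure rates k/n carry the Jeffreys
  95% interval, the 2.5th/97.5th quantiles of Beta(k+½, n−k+½), with the
  conventional boundary overrides (lower bound 0 when k = 0, upper bound 1
  when k = n). Odds are reported as k/(n−k).
* **Sex-stratified contrast.** For two strata with all-positive tables, the
  saturated logistic model (event ~ drug × stratum on the eight cells) has
  interaction MLE ln(OR₁/OR₂) and Wald SE √(Σ 1/cell); the package computes
  this closed form and a two-sided normal p-value. Wald rather than
  likelihood-ratio inference was chosen because it is exact-form, matches
  what standard software reports for interaction terms, and is verified in
  the test suite against an iteratively fitted `glm()` to better than six
  significant figures. Reports of unspecified sex form their own stratum —
  they are reported separately, never silently dropped — and the
  female-vs-male contrast is computed on the two named strata.
* **Exposure contrast.** Exposure rates by sex are compared with the odds
  ratio of exposure (Woolf interval) and Fisher's exact test (two-sided, by
  summing hypergeometric probabilities of tables no more probable than the
  observed one; `stats::fisher.test` provides the computation, and the test
  suite checks it against a full enumeration oracle).

## Trends

`yearly_trend()` counts drug∧event co-reports per receipt year. Published
by-year percentages of this kind are ambiguous about their denominator; the
package defines percent = count / (matching reports with a specified year) ×
100 and always carries that denominator in the result, so the definition is
visible in every output. Reports with an unspecified year are excluded from
the series (but never from contingency tables); zero-count years inside the
observed span are kept so bar charts do not silently skip years. Quarters
are not modeled — receipt year is a plain integer.

## The synthetic generator

`simulation_config()` + `generate_reports()` emulate a spontaneous-report
database with known ground truth:

* Each report independently draws a sex (default mix 55% female, 35% male,
  10% unspecified — a typical spontaneous-report composition), an exposure
  indicator, an index-event indicator, decoy drugs/events, and a receipt
  year.
* The planted association is defined **on the odds scale**: exposed reports
  carry the index event with odds `target_ror` × background odds, i.e.
  P(event | exposed) = ROR·q / (1 − q + ROR·q) with q = `p_event_bg`. This
  makes the generator's truth parameter and the estimand of the ROR
  identical, so parameter-recovery tests are exact in expectation rather
  than approximate.
* Sex-specific exposure odds are solved (one-dimensional root on the log
  scale) so that the female:male exposure odds ratio equals
  `sex_exposure_or` *exactly* and the marginal exposure probability equals
  `p_drug` exactly; unspecified-sex reports receive the marginal odds.
  Defaults mirror the FAERS hydroxychloroquine setting: exposure prevalence
  0.56%, background event rate 10⁻⁴, female:male exposure odds ratio 2.82.
* Decoy drugs and events attach independently of the index pair at a fixed
  2% rate each, so the all-other-reports background is a clean null.
* `surge_year_weights` multiplies the year weights of exposed index-event
  reports only, emulating a notoriety-style late surge in co-reporting.
* Generation uses one explicitly seeded private RNG stream and restores any
  pre-existing global RNG state, so identical configs give byte-identical
  databases and callers' simulations are undisturbed.

What the generator does *not* emulate — and what passing tests therefore do
not establish about real data: duplicate and follow-up report versions,
suspect/concomitant drug roles, dose, correlated drug co-prescription,
indication channeling, and reporting-quality heterogeneity. The generator
validates the statistical machinery, not FAERS itself.

`scaled_report_set()` goes the other way: it materializes a report-level
database from printed 2×2 counts, optionally scaled down, using
largest-remainder rounding so the rounded cells sum exactly to the rounded
total. This lets a printed table drive end-to-end pipeline tests at desk
scale.

## Numerical and design choices

* Counts are stored as doubles: cell products like a·d exceed 2³¹ at
  database scale (a·d ≈ 1.8 × 10¹³ for the packaged table).
* Printed-value comparisons use R's round-half-even at the published
  precision (3 decimals for ROR/CI, 2 for χ² and percents).
* Exposure is evidenced only by a drug row: a report with an empty drug set
  counts as unexposed, matching query semantics of spontaneous-report
  systems.
* Errors are typed (`pvsignal_validation_error`, `pvsignal_input_error`,
  `pvsignal_format_error`, `pvsignal_stat_error`) so the command-line
  wrapper can map them to distinct exit codes (2/3/4/5).
* A query matching no co-report is an answer, not a failure: `run_signal()`
  emits an n = 0, no-signal row with a warning.
* Both the `$`-delimited FAERS ASCII dialect and tab-delimited files are
  supported; the dialect is always explicit, never sniffed.

## Validation strategy and problem sizes

The test suite checks every estimator against an independent route:
contingency counting against a naive per-report loop (up to 10⁵ synthetic
reports), χ² against `stats::chisq.test`, Fisher's test against full
hypergeometric enumeration (totals ≤ 200), the closed-form interaction
against an iterative `glm()` fit, and the Woolf interval against its
operating characteristics: across 200 generator seeds at 200,000 reports
per database with a planted ROR of 50, empirical interval coverage must lie
in [0.92, 0.98], and under a null generator the signal rule may fire in at
most 5% of replicates plus three Monte-Carlo standard errors. These problem
sizes keep each property estimable with useful Monte-Carlo precision while
the full suite runs in a few minutes on one CPU.

## Known limitations

* Sex-stratified odds ratios published without their stratum cells cannot
  be recomputed from a printed pooled table; the package reproduces such
  claims only qualitatively (e.g. that a >100-fold ratio of stratum ORs is
  a significant interaction).
* Published exposure-odds figures whose denominators are not stated may
  disagree in the third significant digit with k/(n−k) on the printed
  margins; the package always reports k/(n−k) and leaves the discrepancy
  visible.
* No PRR, EBGM/MGPS or Bayesian information-component statistics, and no
  multiple-comparison control across drug–event pairs: the intended use is
  a small number of pre-specified queries.
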