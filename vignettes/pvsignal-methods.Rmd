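---
title: "Methods: disproportionality signal detection with pvsignal"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: disproportionality signal detection with pvsignal}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pvsignal)
```

## The problem

Spontaneous adverse-event reporting systems such as FAERS collect
unsolicited safety reports on marketed drugs. They have no denominator —
nobody knows how many patients took the drug — so absolute risks cannot be
estimated. What can be estimated is *disproportionality*: whether a
drug–event pair is reported more often than expected given the drug's and
the event's overall reporting shares. `pvsignal` implements the standard
four-estimator battery used in this literature, together with the data
engineering those estimators depend on (case deduplication, deletion-list
handling, MedDRA coding) and a Weibull model of time-to-onset.

Because the raw database is large, external, and continuously revised, the
package ships a synthetic generator that emulates the quarterly extract
format with known ground truth. All statistical behavior claimed here is
demonstrated by the test suite on that generator's output.

## From raw tables to cases

A quarterly extract is a set of `$`-delimited ASCII tables (DEMO, DRUG,
REAC, OUTC, THER) keyed by `PRIMARYID` (a report version) and `CASEID` (a
case). The same case may appear as multiple report versions, within and
across quarters, and later quarters ship deletion lists of retracted
cases.

Curation follows the hierarchical rule used by FDA-style pipelines: per
`CASEID`, keep the version with the most recent `FDA_DT`; when receipt
dates tie, keep the larger `PRIMARYID`. Two choices here were genuinely
open and are fixed as follows:

* **PRIMARYID comparison** is numeric when every identifier parses as a
  number (the practical case), otherwise lexicographic. "Larger" is
  undefined for mixed identifiers, so the fallback is deterministic and
  documented rather than clever.
* **Deletion lists** are applied wherever they exist, regardless of the
  quarter they shipped with. Restricting them to recent quarters would
  re-admit retracted cases for no benefit.

Reactions are coded from preferred term (PT) to the primary system organ
class (SOC) through a two-column mapping file. MedDRA is licensed and is
not distributed; the package ships a small synthetic *toy* dictionary
(`toy_meddra_map()`) sufficient for the generator's vocabulary and for
tests. Unmapped PTs are retained under the sentinel SOC `"UNMAPPED"` and
reported, never dropped: silent loss of terms is the classic failure mode
of coding steps.

Demographics are taken from the retained version only; when versions of a
case disagree, the latest version wins by construction. Ages are converted
to years (`DEC` ×10, `MON` /12, `WK` /52, `DY` /365.25) and binned as
`<18`, `18–65`, `>65`. Both 18 and 65 fall in the middle bin — the
published table layouts leave 65 ambiguous, and the inclusive-upper
reading is fixed here. A missing unit with a plausible value (0–120) is
treated as years, which recovers usable demographics from lazily coded
reports; the fallback is visible in `pv_defaults()`.

## Contingency tables

For a target drug (defined by name patterns matched against normalized
primary-suspect drug names), each term yields a 2×2 table against the rest
of the corpus:

|                | event | no event |
|----------------|-------|----------|
| target drug    | a     | b        |
| all other drugs| c     | d        |

The counting unit is the **case**: a case reporting the same PT twice, or
two PTs in the same SOC, contributes once to that term's `a`. This
presence/absence convention is the dominant one in FAERS analyses and
guarantees `a ≤ a+b` with margins constant across terms, which the test
suite asserts. The comparator is the whole ingested corpus; no drug-class
restriction is applied.

## The four estimators

With `N = a+b+c+d` and expected count `E = (a+b)(a+c)/N`:

**ROR** — `(a·d)/(b·c)`, interval
`exp(ln ROR ± 1.96·√(1/a+1/b+1/c+1/d))`. Tables with a zero cell get the
Haldane–Anscombe +0.5 on all four cells, and the correction is flagged in
the output rather than hidden.

**PRR** — `[a/(a+b)] / [c/(c+d)]` with the Yates-corrected chi-squared
`Σ(max(|O−E|−0.5, 0))²/E`. The corrected deviation is clamped at zero so a
table exactly at independence scores 0 instead of a spurious positive
value. A zero margin needed by the ratio leaves PRR flagged undefined; no
continuity correction is applied to the ratio itself because its margins
are never zero for observed terms.

**BCPNN information component** — the closed-form posterior of
`IC = log2(p11/(p1·p2))` under independent Beta priors with
`α1 = β1 = 1`, `α = β = 2`, `γ11 = 1`, and the joint prior weight
calibrated so the *prior* IC expectation is zero:
`γ = γ11(N+α)(N+β) / ((a+b+α1)(a+c+β1))`. The lower bound is
`IC025 = E(IC) − 2√V(IC)`. The priors regularize empty cells, so `a = 0`
still yields finite values. The test suite verifies the closed form
against a million-draw simulation of the same Beta posteriors on 200
random tables; because 200 z-scores are compared, the assertion is
multiplicity-aware (≥99% of tables within 3 Monte-Carlo SE, all within 6)
— a formula error would shift every z-score far beyond that band, whereas
a per-table "all within 3 SE" rule fails a correct implementation about
four times in ten by chance alone.

**MGPS / EBGM** — DuMouchel's empirical-Bayes model: `a ~ Poisson(λE)`
with a two-component gamma mixture prior on λ. Marginally each count is a
mixture of negative binomials; the five hyperparameters are fitted by
maximizing that marginal likelihood over all tables of a level
(`nlminb` on log/logit-transformed parameters, started at the
conventional `α1=0.2, β1=0.1, α2=2, β2=4, π=1/3`). The posterior is again
a two-gamma mixture; `EBGM = 2^{E[log2 λ | a]}` (geometric posterior mean)
and `EBGM05` is the 5th posterior percentile, found by root-finding on the
mixture CDF. The root-finding tolerance is scaled to the bracket so that
quantiles many orders of magnitude below 1 (deeply shrunk `a = 0` terms)
keep full relative accuracy; the suite checks agreement with an adaptive
quadrature oracle to 1e-4 relative. The fit is unstratified: no age, sex
or year strata enter `E`. Stratified expectations are a documented
extension point, not a default, matching the unstratified convention of
the four-method battery this package implements.

**Classification** uses the field's threshold battery, all exposed in
`signal_criteria()`: ROR positive iff `a ≥ 3` and the lower CI bound
exceeds 1; PRR positive iff `a ≥ 3`, `PRR ≥ 2`, `χ² ≥ 4` (the MHRA
composite, boundaries inclusive); BCPNN positive iff `IC025 > 0` (strict);
MGPS positive iff `EBGM05 > 2` (strict). The composite flag defaults to
*any* method firing, and can be switched to *all*; published composite
criteria are frequently ambiguous on this point, so it is a visible
configuration rather than a buried constant.

## Time-to-onset

Onset is `event date − earliest primary-suspect therapy start`, in whole
days, with day 0 meaning "immediate". The source fields genuinely vary
across published analyses; this definition is the package's fixed choice
and is recorded in `pv_defaults()`. The policy for imperfect dates is
strict: month- or year-precision dates on either side exclude the case
(reason `partial`), negative intervals exclude it (reason `negative`),
and all exclusions are tallied — the denominators in the output are
therefore always interpretable.

Binning follows the conventional reporting intervals (0, 1, 2, 3, 4–30,
then 30-day bins to 180, 181–365, >365 days) with percentages rounded
half-up to two decimals; `round()`'s banker's rounding would disagree with
published tables at exact .5 remainders, hence `round_half_up()`.
Quantiles are type-7 (R's default linear interpolation).

The Weibull fit maximizes the likelihood via Newton iteration on the
profile equation for the shape,
`g(k) = Σxᵏln x / Σxᵏ − 1/k − mean(ln x) = 0`, to a tolerance of 1e-10,
with the scale then available in closed form. The iteration starts from
the moment estimate `k₀ = π/(√6·sd(ln x))` and halves any step that would
leave the positive domain. The Weibull has positive support, so day-0
events are shifted to 0.5 days by default (`shift_half_day`); `drop_zeros`
is available, and the policy is always echoed in the fit object. Fitting
floored day counts biases the shape slightly downward (about 5% at
shape 1.5, scale 10 d in the suite's end-to-end check) — well inside the
10% recovery band the tests enforce, but worth knowing when interpreting
shape estimates near 1.

## The synthetic generator

`synth_config()` defines the study conditions; `generate_quarter()` draws
them. Per case: demographics from categorical distributions with explicit
missing categories (defaults follow the composition typical of a
consumer-dominated, US-centric corpus: ~62% female, ~57% age unknown,
~70% consumer-reported, ~90% US); one primary-suspect drug from a
ten-drug panel (target share 10%); reactions as independent Bernoulli
draws per configured event with probability `min(1, rr × background)`,
so a planted rate ratio has a precise meaning; onset days as a floored
continuous Weibull (default shape 0.8, scale 10 d — early-weighted, as
acute reactions are), with 75% of cases lacking usable dates, 1% carrying
an impossible (negative) interval and 2% a month-precision start date.
A case whose Bernoulli draws all miss receives the sentinel reaction
`"Unevaluable event"` so that, as in the real database, every case carries
at least one reaction row; under null conditions this filler is
independent of the drug, and it is not used as a planted or evaluated
term in any test.

Duplicates (10% of cases) are emitted as *older* versions — earlier
receipt date, or for half of them the same date with a smaller
`PRIMARYID` — so the keep-latest rule has unambiguous ground truth, which
the suite checks exactly. Deletion lists name 2% of cases. Identical
configurations produce byte-identical files; the generator seeds and then
restores the caller's RNG state.

What the generator deliberately does **not** emulate: drug-name
misspellings and salts, reporting-delay dynamics across quarters,
correlated event co-occurrence, dose fields, and the legacy pre-2012
column layouts. Passing tests therefore demonstrate correctness of the
statistical machinery and the curation rules on well-formed data, not
robustness to free-text chaos in real extracts.

## Problem sizes and test design

The suite's simulation sizes are chosen so each check has real power while
the whole suite stays quick: planted-signal recovery uses twenty 20,000-case
corpora with a rate ratio of 5 (all four methods must flag in ≥95% of
seeds); null calibration uses fifty 4,000-case corpora for the ROR
false-positive bound (≤5%, the one-sided 2.5% Wald event plus the `a ≥ 3`
gate) and five 20,000-case corpora for the mean-IC band (±0.2 bits);
Weibull recovery covers the shape grid {0.5, 1, 1.5, 3} × scale {5, 30}
at n = 5,000 over 20 seeds with a 10% relative-error band. Oracles are
independent of the code paths they check: simulation for the IC closed
form, adaptive quadrature for the EBGM quantile, `chisq.test` for the
Yates statistic, `fitdistrplus` for the Weibull MLE, and sort-based
interpolation for quantiles.

## Known limitations

* Disproportionality is hypothesis-generating: a flagged pair is a
  reporting imbalance, not an incidence estimate or a causal claim.
* The EB prior is fitted on the same tables it then shrinks — standard
  for MGPS, but it means a corpus dominated by one enormous signal can
  distort the prior and over-shrink that signal.
* The strict partial-date policy discards month-precision onsets rather
  than interval-censoring them; an interval-censored likelihood is out of
  scope.
* The toy dictionary maps each PT to one plausible SOC for testing; it is
  not MedDRA, and real analyses must supply a licensed mapping file.
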