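---
title: "Auditing glucometer transcription errors: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Auditing glucometer transcription errors: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(glucaudit)
```

## The audit model

Three record streams describe the same clinical events. The *meter stream*
is authoritative: the glucometer stores each point-of-care result with the
patient's visit identification number (VIN), the test time, and the later
docking time at which the value reaches the laboratory flow sheet. The
*paper log* and the *EMR vital-signs flow sheet* are independent hand
copies, made by technicians and nurses respectively, and the flow-sheet
copy is what informs sliding-scale insulin decisions.

The audit asks four questions per test and source: was the value
documented at all; if documented, does it equal the meter value; if it
differs, does the difference change the insulin dose the protocol
prescribes; and how long did the authoritative value take to reach the
EMR (docking latency).

### Linkage rule

A documented entry corresponds to a meter record when it shares the VIN,
falls on the same calendar date as the test, and lies within a
configurable window (default 60 minutes) *after* the test — a
transcription cannot precede the result it copies. A symmetric window is
available for sensitivity analysis. Candidate pairs are claimed greedily
by ascending offset, ties broken by entry id, making matching
deterministic and globally one-to-one per source. Meter records left
unmatched are *undocumented* in that source; entries left unclaimed are
*orphans* (late documentation, post-discharge anomalies, or stream
errors).

Two consequences of the rule are worth naming. First, a test at 23:30
whose entry lands at 00:10 fails the same-date clause even though it is
within the hour; this is inherent to date-keyed documentation (a paper
log is a dated grid) and is surfaced rather than patched. Second, greedy
nearest-offset matching deliberately is **not** maximum-cardinality
assignment. When a test's own entry is missing, a maximum-cardinality
matcher will steal the delayed entry of a *neighbouring* test to raise the
match count, mislabelling two tests at once; the greedy rule leaves the
test honestly undocumented. The matching oracle tests therefore compare
greedy against brute-force assignment in the regime where delays are
smaller than the spacing between a patient's consecutive tests — there the
two provably coincide — and only structural invariants (conservation,
one-to-one, window containment) are asserted on adversarial instances.

### Exact-recovery guarantee

Within the synthetic generator (below), consecutive tests of one episode
are at least 2 h apart, and every transcription delay is under 120 min
(in-window delays at most 59 min; late, out-of-window delays 61–115 min).
Under forward-only matching this gives an exact-recovery argument: an
entry's offset to its own test is its delay; its offset to any *earlier*
test exceeds the spacing, hence exceeds every delay; to any later test it
is negative. Sorting pairs by offset therefore lists every entry first
with its own test, and no competing claim can precede it — the greedy
matcher reconstructs ownership exactly, so audit labels equal generator
labels record for record. The acceptance suite asserts zero label
mismatches on a full-scale run.

### Error taxonomy and denominators

Any nonzero integer difference between a documented value and the meter
value is a transcription error — no tolerance band, because a one-digit
slip can cross a dosing threshold. Classification is per-source and
independent; a test erroneous in both sources counts in both marginal
categories and in the joint one. Error rates use per-source *documented*
denominators (errors are unobservable where nothing was transcribed),
while undocumented rates use the full test count; documented-in-both
follows by inclusion–exclusion and is verified as an identity.

### Insulin consequence

A sliding-scale protocol is an ordered tiling of half-open glucose bands
`[lo, hi)` mapped to non-decreasing doses, with an optional hold-and-notify
band below a hypoglycemia threshold (default 70 mg/dL). The insulin
assessment computes the dose under the meter value and under the
transcribed value independently; an insulin error is any nonzero dose
discrepancy, or a due dose withheld. Within-band slips never trigger one
(band robustness), so insulin errors are always a strict subset of
transcription errors. The audited unit's real protocol is not public; the
shipped default (0 U below 150; 2/4/6/8 U per 50 mg/dL step; 10 U at 350+)
is a documented synthetic stand-in, and any real audit must supply its own
protocol as configuration. For tests erroneous in both sources the
assessment uses the flow-sheet value, since that is the value nurses dose
from; insulin errors are counted per test, not per administration event.

## Statistics

* **Shift comparison.** Errors versus correct transcriptions, day versus
  night shift (default boundaries 07:00/19:00, half-open, configurable),
  tested per source with the Pearson chi-square with Yates continuity
  correction on the 2×2 table (1 df). The correction is on by default
  because it reproduces the published worked examples (2.9, 3.1, 0.6;
  uncorrected: 3.3, 3.4, 0.9); both variants are exposed and verified
  against the closed-form formula.
* **Test-count comparison.** Diabetic versus nondiabetic per-patient test
  counts compared by the unequal-variance t statistic with
  Welch–Satterthwaite df, computable directly from group summaries. The
  Welch form is the default because the published df (47) matches
  Satterthwaite, not the pooled 135; the pooled variant is available.
* **Quartiles.** All five-number summaries (error magnitudes in mg/dL with
  mmol/L equivalents, docking latency in hours) use linear interpolation
  between order statistics (`quantile` type 7), oracle-tested against a
  sort-and-index implementation.
* **Unit conversion.** mg/dL to mmol/L divides by 18.016 and rounds
  half-up to one decimal; this reproduces every published paired value
  except one (3 mg/dL printed as 0.16 mmol/L, irreproducible under any
  single rounding rule — half-up gives 0.2). Conversion is display-only;
  all computation stays in integer mg/dL.

## The synthetic study generator

The generator emulates the structure of a four-month, single-unit audit:
234 admission episodes producing on the order of 5000 tests, with the
documentation behaviour injected at calibrated rates and recorded as
ground truth. Defaults, with their calibration targets:

| Component | Model | Target |
|---|---|---|
| Cohort | diabetes yes/no/unknown 44:93:97; age N(57.5, 17.4); 56% male | published cohort table |
| Length of stay | lognormal, mean 24.8 d, SD 48.3 d | published mean (SD) |
| Tests per patient | negative binomial by status: mean 60 (SD 126) diabetic, 19 (40) nondiabetic, 6.6 (15) unknown | published count table; unknown-status mean chosen so the cohort total is ~5049 |
| Missingness | coupled per-record draw, marginals 12.04% / 40.88%, joint 4.73% | published undocumented fractions |
| Errors | coupled draw, marginals 2.21% / 8.11%, joint 1.64%; joint errors share one wrong value (a copied transcription) | published error fractions; independence would give a joint rate of ~0.2%, far from the observed 1.64% |
| Error magnitude | 75% small slips of ±1–15 mg/dL, 25% adjacent-digit transpositions, accepted only within ±110 mg/dL and the reportable range | published ranges (−92..92, −110..80) and IQR brackets |
| Docking latency | lognormal with median 5.5 h and mean 8 h, truncated at 56 h | published mean/median/max |
| Transcription delay | gamma (shape 2, scale 8 min) capped at 59 min and at the test's midnight; 15% of missed results leave a late 61–115 min orphan entry | the one-hour audit window; dated paper-log grids |
| Post-discharge anomalies | 40 late entries re-timestamped 1–48 h past discharge | published anomaly count |

Design choices that were genuinely open:

* **Stay length and test burden are coupled.** Counts are drawn through a
  Gaussian copula (correlation 0.9) between log-stay and the count
  quantile, so heavy testers are long stayers. This keeps the
  negative-binomial marginal exact (the mean-60 target holds regardless of
  the stay distribution) while guaranteeing, with a residual clamp that
  binds for well under 1% of draws, that every episode has room for its
  tests at 2 h minimum spacing. Independence instead of coupling would
  force stays to truncate counts and destroy the heavy tail.
* **Missingness means "never usably documented".** The configured miss
  probability is the probability that no same-date, in-window entry exists
  — exactly what the audit can observe — so the audit-recovered rate is a
  clean binomial estimate of the configured value. Late orphan entries and
  post-discharge anomalies are drawn from the missed pool and never
  reclassify a delivered record.
* **Shift structure.** Tests are placed with shift-dependent gaps (day
  U(2,5) h, night U(3,8) h), yielding roughly the published 63:37
  day:night documentation mix; error probabilities are shift-independent,
  consistent with the published null shift comparison.
* **Episodes with zero tests exist** (the count model is not
  zero-truncated, preserving its published mean); audit denominators use
  patients appearing in the meter stream.

What the generator does *not* emulate: physiological glucose dynamics
(values are i.i.d. lognormal around 140 mg/dL), insulin pharmacokinetics,
operator workload structure, duplicate or near-duplicate tests within one
hour, and clock errors between systems. Passing recovery tests therefore
demonstrates the correctness of the pipeline's logic under the stated
timing regime — not robustness to same-hour repeat tests, which real data
can contain and which the linkage rule resolves by nearest offset as a
documented convention.

## Numerical conventions and degenerate inputs

Times are timezone-naive local clock, serialized ISO-8601, held as UTC
internally so arithmetic never crosses a DST boundary; all generated times
are whole minutes. Glucose is integer mg/dL within the reportable range
(default 10–600). Ties in matching break by entry id; quartiles
interpolate linearly; chi-square requires all marginals positive; the
Welch test refuses two zero-SD groups; an empty discrepancy collection
returns an explicit `n = 0` sentinel rather than NA-silence; negative
docking latency is a hard data-integrity error naming the records. CSV
validation collects *all* row-level violations before failing, and the
generator config rejects unknown keys by name.

## Problem sizes

The test suite runs the full generator at its defaults (234 episodes,
~5000–6500 tests; totals are heavy-tailed by design) for the recovery
checks, a 10 000-episode cohort and a 1000-episode all-diabetic stream for
distributional checks, and small constructed instances elsewhere; the
whole suite completes in well under a minute on one core.

## Limitations

The pipeline audits transcription only: meter measurement error, wrong
patient scanning, and the clinical consequences of wrong doses are out of
scope. Per-source error rates condition on documentation, so a source
that documents less is audited on fewer tests — the published flow sheet's
41% missingness means its 8% error rate describes the documented minority.
The default insulin protocol is illustrative; insulin-error counts under
it are not comparable across units with different scales. Matching
resolves same-hour ambiguity by nearest offset; with systematically long
delays and dense testing this convention, like any, can misattribute
entries.
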