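# glucaudit

Auditing hand-transcription of point-of-care blood glucose results in
intensive care units.

## The problem

In many hospitals, bedside glucometers are not interfaced with the
electronic medical record. A technician performs the point-of-care test,
hand-copies the value into a paper log, and a nurse later hand-enters it
into the EMR vital-signs flow sheet — the value that drives sliding-scale
insulin decisions. The meter itself holds the authoritative value, which
only reaches the EMR laboratory flow sheet hours later, when the meter is
docked. Every hand copy can silently miss or corrupt a value, and a
corrupted glucose can change an insulin dose.

`glucaudit` implements this audit as a reusable pipeline for patient-safety
and clinical-informatics teams:

* **Linkage.** Each reference meter record is matched to at most one entry
  per documentation source by visit identification number (VIN), calendar
  date, and a forward one-hour window, greedily by ascending time offset.
  Unmatched meter records are *undocumented* tests; unmatched entries are
  orphans.
* **Error taxonomy.** For a matched test, any nonzero difference
  `transcribed − meter` (mg/dL) is a transcription error, regardless of
  magnitude; tests can be erroneous in the paper log, the flow sheet, or
  both. Per-source error rates use per-source documented denominators.
* **Insulin consequence.** A sliding-scale protocol maps half-open glucose
  bands `[lo, hi)` to doses. An insulin error is
  `dose(transcribed) != dose(meter)`, including a due dose withheld.
* **Statistics.** Day/night shift comparison by Yates-corrected chi-square
  on the 2×2 error table; diabetic/nondiabetic test-count comparison by the
  Welch unequal-variance *t* with Satterthwaite df; docking-latency and
  error-magnitude five-number summaries (linear-interpolation quartiles);
  per-patient error rates and distinct-patients-affected counts.
* **Synthetic studies.** Because real audit data are protected, a
  calibrated generator produces a full study — cohort, meter stream, two
  error-bearing transcription streams, ground-truth labels — so the entire
  pipeline is testable and its recovery properties provable.

## Worked example

```r
library(glucaudit)

study <- simulate_study(generator_config(), seed = 1)
audit <- run_audit(study$meters, study$entries, study$episodes)
audit
```

```
Glucose transcription-error audit
  6247 tests across 131 patient episodes; 60-min forward matching window

Documentation and transcription errors
  paper_log   undocumented  743/6247 (11.89%)  errors 125/5504 ( 2.27%)  per patient 1.0
  flow_sheet  undocumented 2540/6247 (40.66%)  errors 316/3707 ( 8.52%)  per patient 2.4
  both        undocumented  283/6247 ( 4.53%)  errors  49/3247 ( 1.51%)  per patient 0.4
...
Docking latency: mean 7.9 h, median 5.4 h, IQR 3.0-9.9 h, max 56 h
Entries documented after discharge: 40
```

Reading this: of 6247 reference tests, 11.89% never reached the paper log
and 40.66% never reached the flow sheet (4.53% reached neither); among
values that *were* documented, 2.27% and 8.52% were corrupted in transit.
The audit-recovered percentages agree with the generator's configured
missingness (12.04% / 40.88% / 4.73%) and error rates (2.21% / 8.11%) to
within binomial sampling error, and every injected label is recovered
exactly (`test-acceptance.R` proves both).

Individual stages are exposed directly — `match_records()`, `classify()`,
`tally_undocumented()`, `assess_insulin()`, `chisq_2x2()`,
`welch_t_summary()`, `docking_summary()` — as are `stratified_sample()` /
`expand_episodes()` for the shift-stratified, episode-expanded sampling
design, and `run_pipeline()` which persists every intermediate CSV plus a
manifest. A thin command-line wrapper lives at `inst/cli/glucaudit.R`.

For a real audit, supply your three CSV streams (schemas in
`?read_stream`) and your unit's protocol as YAML (`?read_protocol`); the
shipped `default_protocol()` is a documented synthetic stand-in.

## Methods

See `vignettes/glucose-transcription-audit.Rmd` for the full account of
the linkage rule and its exact-recovery guarantee, the coupled
missingness/error model, the calibration targets, and known limitations.
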