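Package: glucaudit
Title: Audit of Glucometer Transcription Errors and Insulin Dose Discrepancies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for auditing hand-transcription of point-of-care blood
    glucose results in intensive care units. Links a reference glucometer
    record stream to independently transcribed documentation streams (a
    paper log and an EMR vital-signs flow sheet) by patient visit, calendar
    date and a one-hour window; classifies transcription errors and
    undocumented tests; translates glucose discrepancies into insulin dose
    discrepancies under a configurable sliding-scale protocol; and reports
    shift-stratified contingency tests, per-patient error rates and meter
    docking latencies. Includes a calibrated synthetic-study generator with
    ground-truth labels so the full pipeline is testable without protected
    hospital data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    graphics,
    utils,
    tools,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
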