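Package: mcpet
Title: Fatigue Apportionment and Lung Mechanics for Musculo-Cardiopulmonary
    Exercise Testing
Version: 0.1.0
Authors@R:
    person("mcpet", "maintainers", email = "mcpet@example.org", role = c("aut", "cre"))
Description: Processes raw signals from musculo-cardiopulmonary exercise
    tests (mCPET) on an isokinetic cycle ergometer: surface EMG envelope
    extraction, per-revolution crank power, the baseline EMG-power
    relationship, and the apportionment of performance fatigue at the limit
    of tolerance into activation fatigue and muscle fatigue. Also computes
    dynamic-hyperinflation endpoints (inspiratory capacity and inspiratory
    reserve volume) from breath-by-breath tables, paired-comparison
    statistics for two-condition trial designs, and a synthetic-trial
    generator with known ground truth for validating every stage of the
    pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
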