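Package: ecogseize
Title: Seizure Detection and Neuronal Excitability Analysis for Chronic
    ECoG Telemetry
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Analysis stack for chronic single-channel electrocorticography
    (ECoG) telemetry in rodent epilepsy models and for the accompanying
    cellular-excitability experiments. Provides a semi-automated seizure
    detector (5-s chunking, 15-dimensional feature extraction, random-forest
    chunk classification, and two-state hidden Markov model smoothing by the
    forward-backward algorithm), automated current-clamp analysis (action
    potential detection by 0 mV crossing and dV/dt criterion, firing curves,
    input resistance, membrane time constant and capacitance), an
    activity-clamp conductance-injection simulator with conductance-threshold
    search, and behavioral and molecular summary statistics (discrimination
    index, delta-delta-CT relative expression, exact 2x2 Fisher test, cohort
    seizure summaries). A synthetic-data module generates every input with
    known ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    minpack.lm,
    ranger,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
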