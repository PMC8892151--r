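Package: gasferm
Title: In Vitro Rumen Gas-Production Measurement: Simulation, Calibration,
    Volumetrics, Kinetics and Repeatability
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for automated in vitro rumen fermentation
    gas-production (GP) measurements. Simulates fermenting bottles with
    head-space pressure sensors under automated (interval or
    pressure-threshold) and manual venting schedules, including CO2
    dissolution and sequestration losses; fits per-sensor linear
    calibrations with hysteresis and leak diagnostics; converts cumulative
    head-space pressure to blank-corrected gas volumes per gram of
    incubated dry matter via the ideal gas law; fits the
    exponential-with-lag kinetic model by bounded nonlinear least squares;
    and estimates variance components of the run-by-feed replicated design
    together with repeatability statistics, technique and feed summary
    tables, and non-fibrous carbohydrate checks of feed composition.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    minpack.lm,
    lme4,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
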