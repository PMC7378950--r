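Package: phenoscale
Title: Cross-Scale Fitting and Comparison of Spring Phenology Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Fits process-based and statistical models of spring plant
    phenology (growing-degree-day and related thermal-forcing models) to
    event dates inferred from status-based monitoring records, and compares
    models parameterised with intensive single-site data against models
    parameterised with sparse broad-scale data. Provides status-record
    cleaning (first-yes/last-no midpoint inference with gap and day-of-year
    filters), eight phenology model predictors, differential-evolution
    fitting with bootstrap parameter distributions and holdout evaluation,
    cross-collection comparison statistics (identity-line coefficients of
    determination, paired RMSE differences with t tests), and a synthetic
    data generator emulating intensive and broad-scale observation
    campaigns.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    DEoptim,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
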