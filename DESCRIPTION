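Package: vitdcosinor
Title: Cosinor Analysis and Seasonal Adjustment of 25-Hydroxyvitamin D
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fits single-component cosinor (harmonic regression) models to
    monthly 25-hydroxyvitamin D (25OHD) measurements and derives the annual
    mean (MESOR), amplitude, peak-trough seasonal variation and peak month
    with delta-method standard errors and Wald confidence intervals.
    Provides covariate contrasts on the annual mean and on seasonal
    variation, anchored prediction of follow-up concentrations from a
    single baseline measurement, season-adjusted annual values, and
    reclassification accounting across a vitamin D sufficiency threshold.
    Includes a synthetic cohort generator emulating a Norwegian
    cardiovascular cohort so the full pipeline is testable without
    patient-level data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
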