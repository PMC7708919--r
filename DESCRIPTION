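Package: pawtherm
Title: Infrared-Thermography Scoring of Arthritis Activity in Mouse Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Standardized quantification of joint inflammation in rodent
    arthritis models from radiometric infrared thermograms. Provides
    emissivity and reflected-temperature correction with blackbody
    calibration quality control, elliptical region-of-interest temperature
    extraction, the per-paw temperature index (paw-to-back temperature
    ratio) and its four-paw total, severity classification and cohort
    inclusion rules, longitudinal treatment-efficacy statistics based on
    trapezoid area under the curve with normality-gated group tests, and a
    synthetic-data generator that emulates phantom thermograms and full
    collagen-induced arthritis cohorts for validation without animal data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    pracma,
    tiff,
    yaml
Suggests:
    optparse,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
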