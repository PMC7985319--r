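Package: znspatial
Title: Inflammation-Adjusted Serum Zinc Status and Geostatistical Mapping
    for National Micronutrient Surveys
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing serum zinc status in national micronutrient
    surveys: BRINDA internal regression correction for inflammation (CRP and
    AGP), classification of zinc deficiency against age-, sex-, draw-time- and
    fasting-specific cutoffs, survey-weighted prevalence estimation, and
    geostatistical mapping of zinc status on great-circle distances with
    robust variogram estimators (Matheron, Cressie-Hawkins, Dowd), weighted
    least squares exponential model fitting, leave-one-out cross-validated
    ordinary kriging, and threshold exceedance probability maps with
    calibrated uncertainty language. Includes a synthetic survey generator
    that emulates the structure of a cluster-sampled micronutrient survey so
    the whole pipeline can be exercised and tested without restricted data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    geosphere,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
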