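Package: skinfoldrel
Title: Skinfold Measurement Protocol, Body Composition and Inter-Observer
    Reliability for Overweight and Obese Pregnant Women
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements a standardised duplicate-reading protocol for
    calliper skinfold thickness measurements (the 7.5 percent third-reading
    rule and mean-of-two / median-of-three aggregation), a population-specific
    linear equation predicting body fat percentage in overweight and obese
    pregnant women from triceps, subscapular and biceps skinfolds, height and
    arm circumference, and an inter-observer reliability analysis based on
    random-observer variance-components models (one-way and two-way
    intraclass correlation coefficients and the standard error of
    measurement). A synthetic-cohort generator with known variance
    components supports end-to-end parameter-recovery validation of the
    whole pipeline.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
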