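Package: edssprog
Title: Disability Class Estimation and Progression Forecasting from
    Administrative Healthcare Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools to estimate Expanded Disability Status Scale (EDSS)
    classes for people with multiple sclerosis from linked administrative
    healthcare databases (drug prescriptions, hospital discharges,
    outpatient encounters, demographics) and to forecast five-year
    disability progression.  Provides a linked synthetic-registry
    generator, claims-based case-finding and six-month-window feature
    construction, a feed-forward softmax classifier for three EDSS
    classes, a feed-forward risk network trained with the Cox partial
    likelihood plus a Breslow baseline cumulative hazard, survival
    evaluation metrics (Harrell's concordance index, integrated Brier
    score, Kaplan-Meier), and k-means risk stratification with
    class-transition projection.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    survival,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
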