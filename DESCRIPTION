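Package: mddcompare
Title: Comparing Minimum Dietary Diversity Indicators for Children Aged
    6-23 Months
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Computes the 7-group and 8-group minimum dietary diversity
    indicators (MDD-7: at least 4 of 7 food groups; MDD-8: at least 5 of
    8 food groups, counting breastmilk as the eighth group) for children
    aged 6-23 months from child-level survey microdata.  Provides
    design-based estimation of prevalences and mean food-group counts
    under stratified cluster sampling via Taylor-linearized variance
    with logit-transformed confidence intervals, lowess smoothing of
    feeding indicators across the 6-23 month age range, country-level
    comparison of the two indicator definitions, a column-mapping ingest
    layer for delimited microdata, and a synthetic survey-cohort
    generator with exactly known population indicator values for
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
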