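Package: admixpheno
Title: Supervised Admixture Estimation and Ancestry-Phenotype Association
    in Three-Way Admixed Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates individual African/European/Native-American admixture
    proportions from panels of ancestry-informative markers under the
    binomial likelihood used by STRUCTURE and ADMIXTURE, with reference
    panels simulated from published source-population allele frequencies.
    Provides marker and individual quality control (exact Hardy-Weinberg
    test, missingness filters, linkage-disequilibrium summaries),
    linear and logistic ancestry-phenotype association models with
    per-10-percent odds-ratio reporting, an ancestry-by-BMI-category
    interaction likelihood-ratio test, a bootstrap resampling power
    analysis, and a calibrated synthetic-cohort generator so the whole
    pipeline is testable without access to individual-level study data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
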