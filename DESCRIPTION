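Package: suvfdg
Title: Body-Habitus-Normalized Standardized Uptake Values for FDG PET
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes standardized uptake value (SUV) metrics for
    18F-FDG PET — SUVbw, SUVlbm, SUVbsa and the body-habitus-normalized
    SUVfdg — from cohort tables of region-of-interest measurements.
    Provides the polynomial body-habitus-normalizer (BHN) model family on
    log inverse liver concentration with ordinary-least-squares fitting
    and AIC/BIC/adjusted-R2 model selection, k-fold cross-validation and
    test-cohort evaluation of metric variability (coefficient of
    variation, Pearson correlation to habitus), and a seeded synthetic
    cohort generator calibrated to published population parameters so the
    whole pipeline is testable without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
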