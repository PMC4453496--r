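Package: grsgrowth
Title: Genetic Risk-Allele Scores and Internally Standardized Growth Across the Life Course
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for relating a combined BMI risk-allele score to internally
    standardized anthropometric z-scores in longitudinal cohort data. Provides
    genotype quality control and mean-allele-imputed score construction
    (call-rate and monomorphism filters, tri-allelic recoding, sibship-sampled
    Hardy-Weinberg tests), internal z-score calibration including a continuous
    sex-specific age-height calibration for weight-for-height, per-child
    longitudinal growth-parameter extraction with inclusion filters,
    mother-clustered random-effects regression, and a three-level mixed model
    with genotype-by-age interactions fitted on orthogonal cubic age
    polynomials. A seeded synthetic-cohort generator with Mendelian genotype
    transmission and recorded ground truth supports calibration and
    parameter-recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    lme4,
    jsonlite,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml,
    vcfR,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
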