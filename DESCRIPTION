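Package: srvis
Title: Sub-Region Variation Intolerance Scoring and Pathogenic-Variant
    Localization Tests
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Divides protein-coding genes into sub-regions (conserved-domain
    alignments plus the unaligned stretches between them, or coding exons),
    scores each sub-region's intolerance to functional variation as the
    studentized residual from regressing common functional variant counts on
    total variant counts in a reference population cohort, and tests whether
    those regional scores predict where pathogenic mutations localize.
    Includes the per-gene multinomial permutation test with a mutation-rate
    null, the genome-wide logistic model with a mutability-weighted
    resampling null and AIC model comparison, a region-shuffle permutation
    test of the biological division, de novo mutation hot-zone enrichment,
    sequence-composition mutation rates, per-region conservation averaging,
    and a fully synthetic cohort generator with planted regional-intolerance
    structure for end-to-end validation.
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
    withr
Config/testthat/edition: 3
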