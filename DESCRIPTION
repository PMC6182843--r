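Package: qpcrstab
Title: Reference-Gene Stability, Efficiency-Corrected Expression and
    Tag-Count Differential Expression for qPCR Validation Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for selecting and validating quantitative PCR (qPCR)
    reference genes and for calling differential expression of target
    transcripts.  Implements amplification-efficiency calibration from
    serial-dilution standard curves, the four standard reference-gene
    stability statistics (geNorm M and pairwise-variation V, the
    model-based NormFinder stability value, BestKeeper descriptive
    statistics and index correlations, and the comparative delta-Ct
    method), a cross-method consensus ranking, efficiency-corrected
    relative expression ratios with a fixed-reallocation randomization
    test, a cross-platform (tag sequencing versus qPCR) agreement rule,
    and Poisson-based tag-count differential expression with the
    Audic-Claverie test.  A seeded synthetic-data module generates
    quantification-cycle matrices, dilution series and tag libraries
    with known ground truth so every stage of the pipeline can be
    exercised and benchmarked without laboratory data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
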