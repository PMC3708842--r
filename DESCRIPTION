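Package: lofadapt
Title: Fitness Analysis of Adaptive Loss-of-Function Mutations in Bacteria
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Statistical pipeline for studying adaptive loss-of-function
    (null) mutations in bacteria. Implements significance calling for
    transposon-footprint fitness selections (loess normalization against
    pre-selection reference arrays, a sign-concordant minimum summary
    statistic, simulated heavy-tailed null distributions, and plug-in FDR
    control), weighted k-means organization of fitness profiles,
    meta-analysis of null-mutation fitness effects by functional class via
    binomial resampling with Benjamini-Hochberg correction, flux balance
    and flux variability analysis of small genome-scale metabolic models
    with gene-protein-reaction deletion tests, replicate-based false
    discovery estimation for differential expression, and doubling-time
    inference from serially diluted growth curves with rank-based strain
    comparisons. Ships generators for every input class with known ground
    truth so the full pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    xml2
Suggests:
    Biostrings,
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
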