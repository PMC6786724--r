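Package: fmtselect
Title: Rational Donor Selection for Fecal Microbiota Transplant Trials
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative tools for rational donor selection in fecal
    microbiota transplantation (FMT) trials. Provides taxon-panel scoring of
    donor stool microbiomes (e.g. summed relative abundance of
    butyrate-producing genera) and tests of association with patient response;
    ranking of donors from stool metabolomics by short-chain fatty acid
    abundance and bile-acid conversion ratio with top-quantile selection; and
    a Monte-Carlo power simulation of retrospective taxon discovery in FMT
    trials, based on signal-to-noise ranking of genera in case-control
    datasets, responder/non-responder subsampling, and Kruskal-Wallis testing
    with Benjamini-Hochberg false-discovery-rate control. Includes readers for
    tab-delimited feature and genus abundance tables with taxonomy-based genus
    collapse, and synthetic-data generators with known ground truth for every
    pipeline stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
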