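Package: mirnaflow
Title: Small RNA Sequencing Analysis of miRNA Expression
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale pipeline for small RNA sequencing analysis of
    microRNA (miRNA) expression: adapter and contamination filtering with
    per-category read accounting, exact genome mapping, rule-based known
    miRNA quantification, novel miRNA prediction by hairpin folding under a
    documented nearest-pair energy model, differential expression by the
    Audic-Claverie conditional Poisson test with Bonferroni correction,
    seed-match and duplex-energy target prediction, hypergeometric
    over-representation analysis with FDR control, and construction of a
    combined miRNA-gene regulatory network with degree-based hub detection.
    Includes a synthetic-data generator that emulates adaptered small RNA
    libraries with known ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    igraph,
    jsonlite,
    stats,
    tools,
    utils,
    withr,
    yaml
Suggests:
    rtracklayer,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
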