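Package: orthoexpr
Title: Cross-Species Ortholog-Aware Expression Comparison
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Builds and confidence-scores ortholog tables between two species
    from genome annotations and Biomart-style homology exports, merges
    cell-type expression profiles across species via orthology, and calls
    expressed, differentially expressed, and uniquely expressed genes with
    RPKM and FDR thresholds.  Includes gene-order-conservation (GOC) and
    whole-genome-alignment (WGA) confidence scoring, shared/unique gene-set
    algebra across cell populations, hypergeometric over-representation
    against gene-set collections, and a paired-genome simulator with planted
    ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    igraph,
    rtracklayer,
    GenomicRanges,
    IRanges,
    yaml,
    withr,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
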