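Package: chromICD
Title: Chromatin Interaction Networks and Interconnected Chromatin Domains
    from HiChIP Loops
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Builds bin-level chromatin interaction networks from significant
    HiChIP loops, annotates network nodes with promoter/enhancer classes and a
    hierarchical chromatin-state vocabulary, and analyses the resulting
    regulatory interactome: degree statistics by contact class, hub detection,
    a node-removal permutation test for cis-regulatory elements, integration
    of promoter connectivity with gene expression (conditional-probability
    deciles, consensus k-means on z-scored expression, single-cell signature
    scoring), classification of transcriptional-memory versus responsive
    genes from nascent RNA, and extraction of per-promoter interconnected
    chromatin domains (iCDs) with connectivity-threshold erosion and
    chromatin-state strength analyses. Ships a seeded synthetic-data
    generator emulating the expected input structure so the whole pipeline is
    testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    igraph,
    GenomicRanges,
    IRanges,
    S4Vectors,
    GenomeInfoDb,
    SummarizedExperiment,
    Matrix,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
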