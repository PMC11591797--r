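Package: ppoperon
Title: Putative Operon Inference from Phylogenetic Profiles, Proximity,
    and Co-Expression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Infers putative operons in a focal bacterial genome by
    combining three lines of evidence: near-identical phylogenetic
    profiles (binary presence/absence of a gene's orthogroup across a
    panel of genomes, compared by Jaccard distance), strand-aware
    genomic proximity, and concordant differential expression between a
    treated and a control condition.  Includes an OrthoFinder
    orthogroup-table reader, a TMM-normalised negative-binomial exact
    test for calling differentially expressed genes from count
    matrices, COG functional-category summaries, delta-delta-Ct
    relative quantification of qPCR confirmations, and a synthetic-data
    generator that plants ground-truth operons so the whole pipeline
    can be validated end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    edgeR,
    rtracklayer,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
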