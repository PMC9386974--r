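Package: methylmark
Title: Epigenetic Marker-Region Discovery from Whole-Genome Bisulfite
    Methylomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A pipeline for calling differentially methylated regions
    (DMRs) between per-CpG methylomes of immune-cell populations, for
    annotating them against gene models, and for distilling them into
    lineage-specific epigenetic marker regions.  Includes pairwise DMR
    segmentation on CpG-level methylation differences, promoter /
    intragenic / intergenic classification with signed TSS distances,
    marker-region extension and exclusivity ranking, Euclidean
    sample-distance clustering, integration of methylation differences
    with expression log2 fold-changes, hyper/hypomethylation contrast
    ledgers between cell-lineage groups, hypergeometric gene-set
    enrichment, expectation-maximisation motif discovery inside DMRs,
    and a seeded synthetic-data generator with planted ground truth
    for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    methods,
    jsonlite,
    yaml,
    ape,
    fgsea,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
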