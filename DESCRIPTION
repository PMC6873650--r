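Package: tevr
Title: Polymorphic Transposable-Element Variants and Flanking-Gene Expression
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis of polymorphic transposable-element insertions (Alu,
    L1, SVA) and their association with flanking-gene expression in a
    population cohort. Provides readers for mobile-element VCF catalogs,
    RPKM expression tables and standard genome annotation; carrier-based
    catalog filtering; an additive-model cis-eQTL scan with
    Benjamini-Hochberg FDR and genotype-randomization validation;
    sliding-window and regulatory-region enrichment tests against
    randomized coordinate sets; karyotype-band density ranking; intra-genic
    orientation concordance; matching of RNA-seq derived insertion calls to
    DNA variants; and a seeded synthetic-data generator with known ground
    truth so the whole pipeline is testable end to end.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    GenomicRanges,
    ggplot2,
    IRanges,
    jsonlite,
    purrr,
    readr,
    rlang,
    rtracklayer,
    S4Vectors,
    stats,
    stringr,
    tibble,
    tidyr,
    tools,
    utils,
    vcfR,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
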