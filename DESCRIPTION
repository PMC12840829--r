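Package: sngco
Title: Identification and Co-Expression Analysis of Specific Neighboring Gene Pairs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies specific neighboring gene pairs (SNGs) - gene pairs
    adjacent in a focal genome whose orthologs are not adjacent in any
    reference species - and analyses their co-expression. Provides
    cross-species adjacency classification from GFF3 annotations and
    ortholog tables, Pearson co-expression statistics with randomization
    nulls and bootstrap standard errors, distance and gene-length binning,
    multi-omics feature construction (ATAC-seq and H3K27ac peak annotation,
    active-enhancer calling, ICE-normalized Hi-C contact extraction, shared
    GO terms and promoter elements, expression divergence), balanced
    logistic-regression modelling of co-expression with repeated train/test
    AUC, variable importance and distance interaction surfaces, and
    gene/module-metabolite association via signed co-expression modules and
    eigengenes. A linked synthetic-data generator plants known structure in
    every layer so the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    readr,
    rlang,
    stringr,
    withr,
    jsonlite,
    ggplot2,
    generics,
    stats,
    utils,
    methods,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    knitr
Config/testthat/edition: 3
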