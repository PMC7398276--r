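Package: methsuite
Title: Feature Annotation of Multi-Tissue Developmental Methylomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline from per-cytosine bisulfite counts to
    developmental methylome features: strand-merged CpG methylation levels
    with bisulfite non-conversion correction, differentially methylated
    site and region (CG-DMR) calling, a bulk-baseline outlier algorithm for
    tissue-specific hypomethylation, loss/gain-of-mCG event accounting,
    large hypomethylated domains, DNA methylation valleys (DMVs),
    random-forest partially methylated domains (PMDs), change-point-based
    non-CpG methylation (mCH) domains with iterative artefact exclusion,
    and hypergeometric / Monte-Carlo enrichment statistics. Ships a
    synthetic multi-tissue, multi-stage methylome generator with a planted
    ground-truth manifest so every caller can be scored against truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    stats,
    utils,
    tools,
    IRanges,
    GenomicRanges,
    randomForest
Suggests:
    testthat (>= 3.0.0),
    mclust,
    yaml,
    knitr,
    rmarkdown
Config/testthat/edition: 3
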