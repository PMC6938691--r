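Package: VariantForest
Title: Random-Forest Quality Control for Variants from Joint Genotyping
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Labels every variant in a multi-sample VCF as high- or
    low-quality by combining stringent hard filters (genotype missing
    rate, Mendelian error rate in trios, Hardy-Weinberg exact-test
    p-value, allele balance of heterozygotes) with a random-forest
    classifier trained on seven sequencing-quality features (mean, SD
    and outlier ratio of depth and genotype quality, and 1-kb window
    GC content). Variants that unambiguously pass or fail the filters
    seed a balanced training set; the fitted forest resolves the
    remaining undetermined variants. Includes the matching evaluation
    metrics (Ti/Tv by known/novel status, microarray genotype
    concordance, multi-allelic and rare-variant fractions) and a
    self-contained synthetic cohort generator for offline testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    IRanges,
    GenomicRanges,
    SummarizedExperiment,
    Biostrings,
    VariantAnnotation,
    randomForest,
    e1071,
    pROC,
    jsonlite,
    yaml,
    withr
Suggests:
    testthat (>= 3.0.0),
    optparse
biocViews: QualityControl, VariantAnnotation, Sequencing, Classification
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
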