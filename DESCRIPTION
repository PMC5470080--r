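Package: bsrseq
Title: Bulked Segregant RNA-seq Analysis of Two-Pool Designs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for bulked segregant RNA-seq (BSR-seq) experiments that
    contrast two phenotypically divergent sample pools. Implements SNP-type
    site validation for pooled allele-depth data, an empirical-Bayes
    beta-binomial linkage-probability score for trait-associated SNPs,
    cross-condition SNP intersection, digital-tag differential-expression
    calling with fold-change binning, and SNP-by-DEG candidate-gene
    integration, together with a seeded synthetic two-bulk data generator
    that provides ground truth for power and calibration studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    SummarizedExperiment,
    Biostrings,
    rtracklayer,
    VariantAnnotation,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
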