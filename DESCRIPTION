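Package: snpcnvr
Title: Copy Number Variable Region Discovery from SNP Array Intensity Data
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Infers copy number variable regions (CNVRs) from SNP-array
    Log R Ratio (LRR) and B Allele Frequency (BAF) signal. Provides a
    pedigree-aware cohort simulator with planted CNV alleles, three
    independent desk-scale CNV callers (a five-state hidden Markov model,
    a sparse-Bayesian-learning segmenter with backward elimination, and a
    recursive likelihood partitioner), multi-caller consensus CNVR
    construction under detected-in-two-animals / three-SNP / two-caller
    filters, Mendelian segregation checking through pedigrees, gene
    annotation by interval overlap, and validation of predicted carriers
    by the 2^-ddCt relative quantification method with FDR/FNR reporting.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
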