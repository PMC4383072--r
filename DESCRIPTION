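Package: rehhscan
Title: Multi-Breed Selection-Signature Scans with Relative Extended
    Haplotype Homozygosity
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Detects genomic regions under recent positive selection from
    phased SNP-chip haplotypes using extended haplotype homozygosity (EHH)
    and relative EHH (rEHH). Provides two-step genotype quality control and
    relatedness pruning for sire-structured livestock panels, linkage
    disequilibrium decay curves, automatic core-haplotype detection via
    D-prime confidence-interval blocks, per-core-allele EHH/rEHH with
    empirical frequency-binned significance, cross-breed shared-region
    detection by production type, positional gene annotation, and a
    Wright-Fisher forward simulator with selective sweeps, pedigree
    structure and genotyping defects for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    optparse,
    stats,
    utils,
    tools,
    methods,
    GenomicRanges,
    IRanges,
    S4Vectors,
    SummarizedExperiment,
    rtracklayer,
    VariantAnnotation
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
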