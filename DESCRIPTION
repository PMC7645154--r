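Package: snpanel
Title: Design and Evaluation of Evenly Spaced SNP Genotyping Array Panels
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for building high-density SNP genotyping arrays from
    population resequencing call sets and for evaluating the resulting
    genotype data. Covers population-level site filtering (minor allele
    frequency, missingness, allele count), probe flank-sequence screening
    (GC content, G/C and A/T run lengths, neighbouring variants), a
    three-stage binning algorithm that thins candidate SNPs to an evenly
    spaced genome-wide panel with gap back-filling, and post-genotyping
    evaluation: call-rate/MAF quality control, conversion-type
    classification, polymorphism accounting by population or species,
    genomic feature density, marker spacing scans, array-versus-sequencing
    genotype concordance, and identity-by-state neighbor-joining
    phylogenies. A seeded simulator of genomes, multi-population variant
    sets and array runs makes the whole pipeline testable without external
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    methods,
    ape,
    vcfR,
    Biostrings,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    rtracklayer,
    S4Vectors,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
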