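Package: HetCorr
Title: Heterozygosity-Aware Hybrid Error Correction for Long Sequencing Reads
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Hybrid correction of long (third-generation) sequencing reads with
    short (next-generation) reads that preserves heterozygous variation. A
    Bayesian per-site classifier models ranked allele counts in a pileup column
    as a chain of sequential binomial draws and decides between homozygosity and
    heterozygosity before any voting-based correction is applied, so that true
    heterozygous alleles are not collapsed onto the majority base. The package
    bundles a diploid read simulator with planted heterozygous SNPs, a greedy
    overlap-layout-consensus assembler for building a pseudo reference from long
    reads, an internal seeded/exhaustive read mapper (plus SAM import),
    zygosity-aware correction rules for mapped and unmapped long reads, and an
    evaluation module that scores heterozygosity retention and quality after
    correction.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    Biostrings,
    IRanges,
    S4Vectors,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    Rsamtools,
    optparse
Config/testthat/edition: 3
biocViews: Sequencing, Alignment, ErrorCorrection, Software
RoxygenNote: 7.3.3
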