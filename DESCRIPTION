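Package: cnvarray
Title: Copy-Number Variant Discovery and Case-Control Association from
    Two-Channel SNP Array Intensities
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: End-to-end copy-number variant (CNV) analysis for two-channel
    SNP genotyping arrays whose normalized signals are not vendor-supplied:
    polar transformation of raw X/Y intensities, canonical AA/AB/BB genotype
    cluster construction, derivation of B allele frequency (BAF) and log R
    ratio (LRR), a distance-aware six-state hidden Markov model for CNV
    segmentation with Baum-Welch training, sample-level quality control
    (call rate, intensity noise, GC-wave correction, identity-by-descent
    relatedness, principal-component ancestry outliers), and case-control
    association of CNV regions with exclusivity screening, local-minimum
    narrowing, exclusion rules and permutation significance. A synthetic
    cohort generator with known embedded CNVs, PCR-saturation compression,
    GC waves, relatedness and population stratification makes every stage
    testable without access to controlled genotype data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.2),
    methods,
    S4Vectors,
    IRanges,
    GenomicRanges,
    SummarizedExperiment
Imports:
    stats,
    utils,
    Rcpp,
    limma
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
biocViews: CopyNumberVariation, SNP, HiddenMarkovModel, QualityControl,
    GenomeWideAssociation
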