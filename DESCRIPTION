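Package: cisAEI
Title: Allelic Expression Imbalance of Heterozygous Somatic Mutations
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Bayesian quantification of allelic expression imbalance (AEI)
    at heterozygous somatic point mutations from paired DNA-seq and RNA-seq
    allelic read counts. Computes maximum a posteriori estimates and 89%
    credible intervals for the DNA allelic log ratio (beta, copy-number
    component), the RNA allelic log ratio (alpha, net expression), and
    their difference (gamma, the cis-regulatory component); decomposes the
    variance of net allelic expression into copy-number and cis-regulatory
    contributions; tests for prevalence of mutant-allele preference;
    calls differential allelic expression (DAE) and daeSNPs from microarray
    allelic intensities in normal tissue and maps candidate regulatory
    variants by genotype stratification; and associates imbalance
    categories with clinical covariates and survival. Includes seeded
    simulators for tumor cohorts and microarray panels so the full
    pipeline is testable without access-controlled data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    SummarizedExperiment,
    VariantAnnotation,
    survival,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr
biocViews: Transcriptomics, GeneExpression, SNP, Bayesian, Survival
Config/testthat/edition: 3
RoxygenNote: 7.3.3
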