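Package: cnpassoc
Title: Copy Number Polymorphism Genotyping and Quantitative Trait Association
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline for association studies of common copy
    number polymorphisms (CNPs) measured on SNP genotyping arrays. Starting
    from marker-level log R ratios and B allele frequencies, the package
    removes GC-correlated genomic waves, segments each sample's genome into
    integer copy number states with a six-state hidden Markov model, applies
    per-sample quality control, builds disjoint genomic intervals and a
    cohort copy-number matrix from CNV breakpoints, genotypes CNP loci with
    a Gibbs-sampled three-component normal mixture, and tests copy number
    against a log-scale quantitative trait with gender-stratified linear
    mixed models, reporting effects as percentage change per copy. A
    synthetic-cohort generator with known ground truth (linked deletion
    haplotypes, genomic waves, plate batch effects, seasonal trait trends,
    sex-specific dosage effects) makes every stage testable without access
    to restricted cohort data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    IRanges,
    lme4,
    purrr,
    rlang,
    S4Vectors,
    stats,
    tibble,
    tidyr,
    utils
Suggests: testthat (>= 3.0.0), jsonlite, withr
Config/testthat/edition: 3
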