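Package: ngsGroupTest
Title: Group Association Tests for Sequencing Data Without Genotype Calling
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Score tests for the association of a group of genetic variants
    with a complex phenotype under a generalized linear model, computed
    directly from next-generation sequencing read data (genotype likelihoods)
    without calling genotypes. Provides the joint significance test for a
    group of common variants (chi-square, dg degrees of freedom) and the
    variable collapse test for a group of rare variants (1 degree of freedom),
    each for continuous (linear), binary (logistic) and count (Poisson)
    phenotypes; genotype-based chi-square/F and weighted burden comparator
    tests; one-step EM and two-step genotype-calling estimators of allele
    frequencies from genotype likelihoods; readers for BEAGLE genotype
    likelihood and VCF GL/PL formats; and a seeded simulator of low-coverage
    sequencing studies with Type I error and power benchmarking utilities.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    VariantAnnotation,
    pracma,
    optparse,
    jsonlite,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
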