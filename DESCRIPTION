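Package: ROHmix
Title: Simulation and Quantification of Extreme Inbreeding from Runs of
    Homozygosity
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools to quantify extreme inbreeding (offspring of first- and
    second-degree relative matings) from SNP genotypes. Simulates inbred
    pedigrees over a genetic map with Bernoulli-per-interval recombination and
    founder-origin tracking, detects runs of homozygosity (ROH) with a
    sliding-window caller, computes genomic inbreeding coefficients (F_ROH,
    F_ROH-X, F_UNI), models ROH length distributions as shifted exponential
    mixtures selected by BIC, deconvolves parent-offspring versus full-sib
    mating by maximum likelihood, and estimates inbreeding depression and
    inbreeding load on synthetic phenotypes.
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
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
biocViews: Genetics, SNP, Software, StatisticalMethod
RoxygenNote: 7.3.3
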