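Package: soyepi
Title: Population Structure, Mixed-Model GWAS and Bayesian Multilocus
    Epistasis for Soybean Flowering Time
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An end-to-end toolkit for dissecting a quantitative trait
    (days to flowering) in structured, highly inbred crop panels.
    Provides population-structure and diversity statistics
    (identity-by-state and Kimura two-parameter distances, BIONJ trees,
    principal coordinates, linkage-disequilibrium decay, windowed
    nucleotide diversity and Weir-Cockerham Fst, method-of-moments
    inbreeding coefficients), a compressed mixed-linear-model
    genome-wide association scan with P3D variance components,
    biologically filtered candidate marker-set construction from
    homology hits, and a Bayesian partition model (Dirichlet-multinomial
    genotype blocks with a conjugate Gaussian phenotype likelihood)
    searched by Markov chain Monte Carlo to detect multilocus epistatic
    interactions, verified by two-locus regression tests. A genotype and
    phenotype simulator with Balding-Nichols divergence, tunable
    inbreeding and exponentially decaying linkage disequilibrium
    generates fixtures with the statistical structure the analysis
    assumes.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    ape,
    vcfR,
    rtracklayer,
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
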