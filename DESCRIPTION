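Package: ZWstrata
Title: Sex-Linked Sequence Discovery and Evolutionary Strata Dating for
    ZW Chromosomes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for coverage-based discovery of W-linked sequence from
    female/male read-depth profiles, Nei-Gojobori (1986) estimation of
    synonymous and nonsynonymous divergence between Z and W gametologs,
    assignment and dating of evolutionary strata under a sex-specific
    mutation-rate model, GC/CpG/repeat composition profiling with
    Kimura-distance element ages, refugium and toxicity indices for
    transposable elements, and gene-content evolution statistics
    (copy number, decay rates, translocation and expression rules).
    Includes synthetic-data generators that emulate the statistical
    structure of female-heterogametic genomes so every analysis can be
    exercised and calibrated without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    Biostrings,
    car
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
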