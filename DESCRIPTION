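Package: enhburden
Title: Rare-Variant Burden Testing in Enhancer and Coding Regions
Version: 0.1.0
Authors@R: person("enhburden", "developers", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Case-control rare-variant association testing for sets of
    regulatory enhancers linked to coding genes, and for coding regions.
    Implements cohort quality control (missingness, Hardy-Weinberg exact
    test in controls, differential missingness, depth outliers), variant
    prioritization by population allele frequency and conservation score,
    Beta-density MAF weighting, SKAT and the optimal unified SKAT-O test
    with exact mixture-of-chi-square p-values, Firth penalized logistic
    regression for coding burden, carrier and risk-ratio summaries,
    genomic-inflation diagnostics (lambda GC / lambda 1000, Q-Q tables),
    position-specific scoring-matrix scanning of wild-type versus mutant
    enhancer sequences, and a seeded synthetic-cohort simulator so the
    whole pipeline is testable without access-controlled genotype data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    jsonlite,
    BiocGenerics,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings,
    SummarizedExperiment,
    VariantAnnotation
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
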