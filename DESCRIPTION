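Package: numtshadow
Title: Dual-Reference Assessment of NUMT Interference in Mitochondrial
    Heteroplasmy Calling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Simulation and analysis toolkit for quantifying how nuclear
    mitochondrial sequences (NUMTs) distort deep-sequencing estimates of
    mitochondrial heteroplasmy. Generates synthetic worlds (circular mtDNA,
    divergent NUMT insertions in nuclear contigs, planted heteroplasmies),
    simulates the common mtDNA enrichment strategies (long-range PCR,
    multi-amplicon PCR panels and multiple displacement amplification),
    produces error-bearing reads, maps them competitively against a
    mitochondria-only versus a combined mitochondrial-plus-nuclear
    reference, and compares per-site allele-frequency calls between the
    two modes: concordance classification, reference-exclusive variants,
    positional clustering against NUMT coverage, and exact proportion
    tests between experimental conditions.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    Biostrings,
    IRanges,
    jsonlite,
    withr
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    vcfR
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
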