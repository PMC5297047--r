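Package: xspec
Title: Cross-Species Somatic Mutation Consensus, Validation and Spectrum Analysis
Version: 0.1.0
Authors@R:
    person("Repo", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for the downstream analysis of tumor/normal somatic point
    mutation calls in a cross-species (zebrafish to human) oncogenomics
    setting: dual-caller consensus and quality-quartile stratified validation
    panel design, orthogonal validation of candidate loci by deep readcounts
    with explicit allele-fraction classification rules, ROC evaluation of
    caller quality scores, genome-wide mutation-burden extrapolation from
    validation rates, pyrimidine-normalized substitution spectra with
    trinucleotide context and mutational-signature similarity, genomic-region
    annotation, ortholog mapping, gene-set overlap testing, and per-gene
    mutation-frequency comparison between patient cohorts. A fully seeded
    synthetic-data generator emulates every input with known ground truth so
    the entire pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.0)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    VariantAnnotation,
    SummarizedExperiment,
    rtracklayer,
    jsonlite,
    stats,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
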