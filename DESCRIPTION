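Package: scellcn
Title: Single-Cell Copy-Number and SNP-BAF Profiling of Whole-Genome-Amplified Tumor Cells
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Reusable pipeline for copy-number and allelic-state analysis of
    single whole-genome-amplified (WGA) tumor cells from shallow sequencing:
    uniquely-mappable-position masks, variable-width bins holding a fixed count
    of unique positions, pseudocounted focal read-depth logR with Loess GC
    correction and median normalisation, exact penalised piecewise-constant
    (PCF) segmentation, integer copy number via 2^logR x Psi, digital SNP
    B-allele fractions with segment-level allelic-state calls (including
    copy-neutral LOH), an aCGH-mode probe-track processor, and concordance /
    clonality comparison of a single disseminated tumor cell against its
    primary tumor. A synthetic tumor and single-cell read generator (subclonal
    event plans, WGA amplicon noise, GC bias, PCR duplicates, adapter-prefixed
    reads, SNP allele counts, bulk probe tracks) makes every stage testable
    without external data.
License: MIT
Encoding: UTF-8
Imports:
    Biostrings,
    IRanges,
    Rcpp,
    S4Vectors,
    jsonlite,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
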