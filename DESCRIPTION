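Package: SymbioNet
Title: Host-Symbiont Partner Inference from Metagenomic Co-Occurrence and
    Horizontal Gene Transfer
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Infers candidate host-symbiont partnerships for ultra-small,
    symbiotic prokaryotes (such as DPANN archaea) directly from metagenomic
    community data. Builds marker-gene (rpS3) OTU profiles by greedy
    95%-identity clustering, estimates compositionality-aware basis
    correlations between OTU abundances (a SparCC-style log-ratio variance
    estimator) with permutation pseudo-p values, detects directional
    interphylum horizontal gene transfer from self/close/distal homology
    score distributions, screens for recent xenologs (high-identity
    transferred genes) against companion community genomes, and integrates
    both evidence lines into ranked partner hypotheses. Includes a
    synthetic-data generator with planted ground truth (correlated
    communities, planted transfer events, planted single-copy markers) and
    per-genome assembly statistics (single-copy-gene completeness, N50,
    GC content, coding density, overlapping genes).
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
    Biostrings,
    SummarizedExperiment,
    igraph,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    rtracklayer,
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
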