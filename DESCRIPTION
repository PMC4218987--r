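Package: sortseqrep
Title: Sort-Seq DNA Replication Profiling: Simulation, Processing and Origin Prediction
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for genome-wide DNA replication profiling from sorted
    S-phase sequencing ("sort-seq"). Simulates origin firing and fork
    progression with passive replication, generates restriction-fragment
    read-count matrices emulating FACS-sorted S versus G1/G2 libraries,
    implements the fragment-level filtering and normalization cascade
    (length and depth filters, per-chromosome copy-number correction,
    length-bias removal, division by the mean G1/G2 signal, z-scoring),
    denoises count matrices by low-rank SVD reconstruction, smooths
    profiles with a Savitzky-Golay filter, quantifies profile sharpness
    (extrema, activation heights, autocorrelation decay, between-strain
    correlation), and evaluates peak-based origin prediction with a
    binomial tail enrichment statistic.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    methods,
    jsonlite,
    BiocGenerics,
    Biostrings,
    IRanges
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
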