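Package: ffmea
Title: Burst Propagation, Functional Connectivity, and Transmission
    Fidelity in Two-Layer Feed-Forward MEA Recordings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for microelectrode-array (MEA) recordings of
    two cortical populations coupled through axonal microtunnels. Provides a
    ground-truth-annotated simulator of two-layer feed-forward recordings
    (Poisson background, network bursts, tunnel conduction), spike detection
    and PCA/k-means sorting from raw traces, summed-burstlet network-burst
    detection with Layer I to Layer II propagation matching, directionality
    and functional-connectivity inference (cross-correlograms on tunnel
    electrode pairs, conditional Granger causality with Benjamini-Hochberg
    FDR control), and transmission-fidelity profiling with the normalized
    Victor-Purpura similarity and a Pearson-correlation van Rossum variant.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
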