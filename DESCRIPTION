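Package: spikematch
Title: Comparison, Consensus Curation and Quality Metrics for Spike Sorting Outputs
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools for comparing the outputs of extracellular spike sorters:
    spike-train agreement scoring with tolerance-window matching, optimal
    (Hungarian) unit assignment, ground-truth evaluation with per-unit
    performance measures and unit classification, multi-sorter agreement
    graphs and consensus (ensemble) curation, and a set of per-unit quality
    metrics (SNR, ISI violations, amplitude cutoff, isolation distance,
    L-ratio, d-prime, nearest-neighbour contamination, silhouette, drift).
    Includes lazy preprocessing of raw recordings, waveform/template/PCA
    postprocessing, seeded synthetic benchmark generators, provenance
    capture, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    graphics,
    igraph,
    jsonlite,
    signal,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
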