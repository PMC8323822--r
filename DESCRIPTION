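Package: effconn
Title: Effective Connectivity Reconstruction from Spike Trains by
    Super-Selective Correlation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Reconstructs the effective (direct and causal) connectivity of
    spiking neuronal networks, such as those recorded on multi-electrode
    arrays, from spike trains. Pairwise cross-correlograms are computed and
    smoothed, correlation peaks are detected with their delays, amplitudes
    and widths, and indirect or apparent links are pruned by a
    super-selection rule operating on cyclic correlation triangles: when the
    three delays of a triangle nearly cancel, the peak of minimum amplitude
    is discarded as a false positive. Reconstructions across a grid of
    analysis parameters are combined into a connection frequency matrix and
    thresholded to yield the final directed network. The package ships an
    Izhikevich spiking-network simulator with per-edge conduction delays for
    validation against known ground truth, deterministic spike-motif
    fixtures, evaluation metrics (true/false positive rates, confidence
    indicator, accuracy), graph-theoretic network descriptors, a
    receiver-probability estimate of neuronal signalling roles, and a
    PCA/k-means spike sorter for waveform snippets.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    igraph,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
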