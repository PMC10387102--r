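Package: mfnet
Title: Spike-Train Analysis for Microfluidically Organized Neuronal
    Networks on Microelectrode Arrays
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: End-to-end analysis of multi-channel microelectrode-array
    (MEA) recordings from neuronal cultures grown in microfluidic
    compartments (somatic chambers, neurite microchannels, synaptic
    chamber). Provides column-group re-referencing, Bessel bandpass
    filtering, robust MAD-threshold spike detection with dead time,
    interspike-interval burst detection, binned cross-correlation with
    jitter-surrogate significance, and compartment-aware short-term and
    delayed functional connectivity graphs with afferent/efferent node
    roles. Includes a synthetic MEA-recording generator with known
    ground-truth spike trains, propagation edges and delays for
    validating every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    jsonlite,
    Rcpp,
    signal,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    xml2
Config/testthat/edition: 3
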