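Package: cyclicity
Title: Cyclicity Analysis of Multichannel Time Series
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Reparametrization-invariant lead-lag analysis of multichannel
    recordings via pairwise oriented areas (level-2 iterated path integrals).
    Builds the skew-symmetric lead matrix, extracts the temporal ordering of
    channels swept by traveling waves ("ripples") from the constellation of
    its leading eigenvector, ranks channels by an elliptic norm fitted to the
    constellation, and detects lead-lag reversals and burstiness in
    oriented-area trajectories with one-dimensional sublevel-set persistent
    homology. Includes a chain-of-offsets simulator (periodic waves, solitary
    ripple trains, and task-block designs) that provides ground truth for
    every stage of the pipeline.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
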