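Package: synquant
Title: Optical Quantal Analysis of Single Synaptic Vesicle Fusion Events
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for detecting and quantifying single synaptic-vesicle
    fusion events in pH-sensitive fluorescence recordings (pHluorin,
    pHTomato) and postsynaptic calcium indicator traces (GCaMP).
    Implements moving-average threshold detection of spontaneous
    transients against a local-baseline noise estimate, single-exponential
    decay fitting, constrained quantal Gaussian mixture decomposition of
    amplitude histograms, a two-event temporal-overlap model of apparent
    multivesicular amplitudes, dual-channel pre/post event coincidence
    analysis with photobleach correction, and per-synapse spontaneous
    rate versus evoked fusion probability statistics. A ground-truth
    synthetic trace generator emulating Poisson-timed quantal events,
    re-acidification decay, folimycin staircase and Tris slowed-decay
    conditions supports end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    minpack.lm,
    fitdistrplus
Suggests:
    testthat (>= 3.0.0),
    tiff,
    yaml,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
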