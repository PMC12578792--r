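Package: natfnirs
Title: Sustained-Attention Hemodynamics from Naturalistic Infant fNIRS
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools to isolate sustained-attention-related hemodynamic activity
    from naturalistic infant functional near-infrared spectroscopy (fNIRS)
    recordings. Implements behavioral look-bout parsing and sustained-attention
    event extraction (100 ms look-away merging, >8 s threshold, 15 s cap, 5-event
    participant gate), a HOMER-style preprocessing chain (intensity pruning,
    optical density, db2 wavelet and spline motion correction, 0.01-1 Hz
    zero-phase band-pass, modified Beer-Lambert inversion), attention-phase
    active-baseline epoching with onset shifting and interstimulus gating,
    peak-window chromophore statistics, ROI and channel-wise one-tailed
    inference with false-discovery-rate control, a cluster-mass sign-flip
    permutation test over the channel adjacency graph, and an onset-shift
    validation harness. A synthetic-data generator with a two-wavelength
    optical forward model provides ground truth for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    signal,
    yaml,
    jsonlite,
    data.table
Suggests:
    testthat (>= 3.0.0),
    igraph,
    withr
Config/testthat/edition: 3
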