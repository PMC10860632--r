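Package: engulfr
Title: Quantification of Microglial Engulfment, Dorsal-Horn Neuron
    Classification, and Estimation Statistics
Version: 0.1.0
Authors@R: person("Engulfr", "Developers", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: A reproducible pipeline for quantifying microglial engulfment of
    primary-afferent terminals from multi-channel 3D fluorescence volumes
    (triple-colocalization of fiber, lysosome and microglia signal), counting
    synaptic puncta by 3D connected-component segmentation, classifying
    dorsal-horn wide-dynamic-range neurons into adapting and nonadapting
    groups from spike trains via an adaptation ratio with exact 1-D 2-means
    clustering, and computing estimation statistics (bias-corrected and
    accelerated bootstrap confidence intervals for unpaired mean differences,
    permutation tests, Welch's t). Includes seeded synthetic-data generators
    (engulfment phantoms with voxel-exact ground truth, non-touching puncta
    fields, inhomogeneous-Poisson spike trains, two-group cohorts) so the
    whole pipeline is testable without any imaging data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    igraph,
    jsonlite
Suggests: testthat (>= 3.0.0), optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
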