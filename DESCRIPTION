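Package: tfus
Title: Transcranial Focused Ultrasound Simulation, Phase Aberration
    Correction, and Surrogate Modeling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Desk-scale toolkit for two-dimensional transcranial focused
    ultrasound planning research. Generates procedural skull-slice
    phantoms in Hounsfield units, maps them to acoustic media, and
    solves linear heterogeneous acoustic propagation for a flat phased
    array with a staggered-grid finite-difference time-domain solver.
    Computes per-element phase aberration corrections by time reversal
    and by straight-ray time-of-flight, evaluates focal spots with a
    full metric suite (half-maximum masks, fitted ellipses,
    intersection-over-union, modified Hausdorff distance, axial and
    lateral projections), and trains a reduced-scale multi-task
    LSTM-convolutional surrogate network that predicts normalized
    pressure fields, peak pressures, and phase correction vectors
    directly from skull rasters.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    png,
    RNifti
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
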