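Package: complexcortex
Title: Encoding and Decoding of Naturalistic Stimulus Complexity in Sensory Cortex
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Objective complexity measures for naturalistic images (mean maximum
    Lab gradient, lossless PNG size, PHOG self-similarity) and music (lossless and
    lossy codec sizes, onset event density), preparation of trial-by-voxel fMRI
    response matrices, multi-subject Procrustes hyperalignment into a common
    representational space, per-voxel linear encoding models, ROI-level ridge
    decoding with the regularization path parameterized by effective degrees of
    freedom and selected by leave-one-out cross-validation, permutation
    significance testing with bootstrap standard errors, and the overlap and
    sensitivity summaries that characterize complexity representations across
    regions of interest. Includes a synthetic-data generator so the full pipeline
    can be exercised end to end without access to the original stimuli or scans.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    grDevices,
    stats,
    utils,
    png,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
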