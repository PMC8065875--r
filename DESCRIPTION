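Package: dceDRO
Title: Digital Reference Objects for Simulating Subtle Blood-Brain Barrier
    Leakage Measurement with DCE-MRI
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: A four-dimensional computational model of dynamic
    contrast-enhanced MRI (DCE-MRI) measurement of subtle blood-brain
    barrier leakage. Generates digital reference objects (DROs) from a
    labelled multi-tissue head phantom with known Patlak parameters
    (permeability-surface area product PS and plasma volume fraction vP),
    simulates the acquisition process (starting-position randomisation,
    gross rigid-body motion, 3D Cartesian k-space sampling with
    field-of-view suppression, composite-k-space motion artefacts and
    complex Gaussian noise), and recovers voxelwise parameter maps and
    region-of-interest estimates so that the error introduced by each
    spatio-temporal effect can be quantified. Includes rigid realignment,
    segmentation propagation, mask erosion, k-space low-pass filtering,
    four summary estimators and a Monte-Carlo experiment harness.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    RNifti,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
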