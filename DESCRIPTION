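Package: neurotomo
Title: Synthetic Micro-CT Simulation and Quantification of Sparsely
    Stained Neurons
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: An end-to-end, fully synthetic test bench for
    synchrotron-style X-ray microtomography of Golgi-Cox stained brain
    tissue. Generates phantom volumes of sparsely mercury-impregnated
    neurons with known ground truth, simulates parallel-beam projection
    including flat fields, photon noise and offset-rotation-axis 360
    degree extended field-of-view scans, stitches and reconstructs them
    by filtered back-projection, denoises with a non-local means filter,
    segments brain mask, cell bodies and neurons by threshold-and-
    morphology recipes suited to Golgi-Cox contrast, and quantifies cell
    densities with ground-truth validation and two-group Student's t
    statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    tiff,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
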