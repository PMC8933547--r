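Package: speckledemix
Title: Demixing and Fingerprint-Based Reconstruction of Fluorescence
    Speckle Images Acquired Through Scattering Media
Version: 0.1.0
Authors@R:
    person("Fernand", "Okkerse", email = "f.okkerse@posteo.net",
           role = c("aut", "cre"))
Description: Non-invasive fluorescence imaging through strongly scattering
    layers from stacks of low-contrast speckle frames acquired under
    varying random illumination.  Each independent emitter of a hidden
    fluorescent object produces a fixed speckle "fingerprint" on the
    camera; every frame is a non-negative mixture of these fingerprints
    with random illumination weights.  The package demixes the
    fingerprints by non-negative matrix factorization (with residual-based
    rank estimation), estimates pairwise emitter displacements by
    total-variation-regularized deconvolution of fingerprint pairs,
    composes displacements along a shift graph so that reconstruction can
    extend beyond a single optical memory-effect (isoplanatic) patch, and
    stitches partial images into a global reconstruction.  A physics-based
    simulator of memory-effect-correlated speckle fingerprints provides
    ground truth for validation, so the whole pipeline is testable without
    experimental data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    igraph,
    jsonlite,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
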