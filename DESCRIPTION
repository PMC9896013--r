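Package: brainprint
Title: Brain Fingerprinting with Resting-State Functional Connectivity
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for subject identification ("brain fingerprinting") from
    resting-state functional connectivity matrices measured with fNIRS or
    fMRI. Provides a synthetic multi-subject cohort generator with known
    ground-truth connectivity signatures, an fNIRS preprocessing chain
    (SNR-based quality control, optical-density conversion, hybrid
    spline/wavelet motion-artifact correction, modified Beer-Lambert law,
    band-pass filtering, PCA removal of global physiology), AR prewhitening
    with BIC order selection, Pearson functional-connectivity matrices,
    three identification engines (Pearson matching, affine-invariant
    geodesic distance on SPD matrices, ridge linear classifier),
    leave-one-out resampling experiments over training runs and ROI
    subsets, an exponential accuracy-saturation model with ROI-threshold
    analysis, and rank-based statistical reporting.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
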