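Package: annhypr
Title: Cascade Patch ANN and HYPR Denoising for Reduced-Count Dynamic PET
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Spatiotemporal denoising of reduced-count (low-dose) dynamic
    PET image series by a patch-based single-hidden-layer artificial neural
    network applied in cascade, followed by HYPR composite-ratio filtering,
    together with the surrounding workflow: a synthetic dynamic brain
    phantom driven by one-tissue-compartment kinetics with Poisson count
    noise and multinomial count thinning, comparator filters (3D Gaussian,
    4D spatiotemporal non-local means), voxel-wise basis-function kinetic
    fitting of K1, k2 and VT parametric maps, and an evaluation suite
    computing ensemble normalized standard deviation, regional relative
    error, noise reduction and Poisson dose-equivalence.
License: MIT
Encoding: UTF-8
Imports:
    RNifti,
    Rcpp,
    jsonlite,
    stats,
    utils,
    graphics
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
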