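Package: bsb1map
Title: Accelerated 3D Bloch-Siegert B1+ Mapping by Two-Step Variational
    Reconstruction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reconstructs quantitative B1+ (transmit radio-frequency field)
    maps from highly subsampled Cartesian Bloch-Siegert shift acquisitions.
    A first convex problem recovers the morphology-bearing complex image from
    the positive-offset data under second-order total generalized variation
    (TGV2) regularization, solved by a primal-dual splitting algorithm; a
    second convex problem recovers the spatially smooth doubled
    Bloch-Siegert phase field from the negative-offset data under H1
    regularization, solved by conjugate gradients on the normal equations.
    Includes centered Fourier and finite-difference operators with exact
    adjoints, Cartesian phase-encode subsampling pattern generators (block,
    polynomial-density and Gaussian-density), Bloch-Siegert pulse physics, a
    multi-coil phantom and acquisition simulator, Walsh-style adaptive coil
    sensitivity estimation and combination, a zero-padded low-resolution
    baseline, and error-map evaluation utilities.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    graphics,
    grDevices,
    RNifti
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
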