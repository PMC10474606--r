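Package: stargrasp
Title: Slice-Parallel XD-GRASP Reconstruction of Respiratory-Resolved 4D-MRI
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reconstructs respiratory-resolved 4D-MRI from golden-angle radial
    stack-of-stars acquisitions using the XD-GRASP compressed-sensing model:
    a respiratory surrogate is extracted from the k-space centre by
    self-gating (baseline PCA or angle-dependent correction with coil
    rejection), spokes are sorted into amplitude bins (non-overlapping or
    overlapping), and per-slice total-variation regularised reconstructions
    are solved in parallel with a nonlinear conjugate-gradient method after
    FFT decoupling along the Cartesian kz axis. Includes gridding-based
    non-uniform FFT operators with an exact non-uniform DFT oracle, a moving
    phantom simulator producing exact synthetic k-space with ground truth,
    SSIM-based volume comparison, Amdahl-law timing predictors, a raw-data
    container format, NIfTI export, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    RNifti,
    jsonlite,
    parallel,
    stats,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
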