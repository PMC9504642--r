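Package: vtatlas
Title: Dynamic Spatiotemporal Atlases of the Vocal Tract from Multi-Plane
    Real-Time Image Series
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Construction and evaluation of anatomically neutral, dynamic
    spatiotemporal atlases of the vocal tract from 2D multi-plane real-time
    magnetic resonance image series of consonant-vowel syllables. Provides
    affine and cubic B-spline free-form-deformation image registration with
    transform averaging, histogram matching, groupwise reference-space
    construction from silence frames, piecewise-linear temporal alignment of
    consonant and vowel segments onto reference durations, adaptive Gaussian
    kernel synthesis of atlas frames at arbitrary time points, four-fold
    cross-validated cross-correlation similarity evaluation, landmark-based
    vocal-tract measurements, and a seeded synthetic multi-speaker phantom
    generator with known ground-truth deformations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    EBImage,
    Matrix,
    RNifti,
    Rcpp,
    jsonlite,
    stats,
    tiff,
    tools,
    utils
LinkingTo:
    Rcpp
Suggests:
    knitr,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
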