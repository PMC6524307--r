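Package: mvctenhance
Title: Megavoltage CT Image Enhancement by Block Matching and
    Discriminative Feature Representation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Enhancement of low-quality megavoltage CT (MVCT) slices for
    image-guided and adaptive helical TomoTherapy. Implements block
    matching of similar 8x8 patches into 3D groups, sparse coding of each
    group over a discriminative dictionary split into high-quality and
    noise-model sub-dictionaries (orthogonal matching pursuit),
    collaborative 3D hard-threshold filtering (biorthogonal 1.5 wavelet
    per block plus an orthonormal transform along the stack), and
    weighted aggregation into the final image. Also provides a plain
    BM3D arm for comparison, contrast-to-noise-ratio and Canny-edge
    evaluation, a Hounsfield-unit density-stability check, and a
    Catphan-like digital phantom generator with a simulated MVCT/KVCT
    noise model so that the whole pipeline is testable without clinical
    scans. Readers and writers for NIfTI, a minimal uncompressed DICOM
    subset, and a raw-binary fixture format are included.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    knitr,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
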