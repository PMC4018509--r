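Package: swtreg
Title: Rigid CT/CBCT Registration with Stationary Wavelet Gradient Images
    and Weighted Normalized Mutual Information
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Rigid (2D translation plus in-plane rotation) registration of
    planning CT and setup cone-beam CT slices for image-guided radiotherapy.
    Gradient images are synthesized by a stationary (undecimated, a-trous)
    wavelet transform: approximation bands are zeroed and the detail bands
    are inverse-transformed, yielding an edge-dominant companion image.
    Alignment is scored by a logistic-weighted combination of the normalized
    mutual information of the intensity images and of the gradient images,
    and optimized with Powell's direction-set method using Brent line
    searches. Includes DICOM/PNG/TIFF input, grid resampling, a synthetic
    anatomical phantom generator with CBCT-like degradation, and experiment
    harnesses for preset-transform recovery and shift-linearity protocols.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    png,
    tiff,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0), optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
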