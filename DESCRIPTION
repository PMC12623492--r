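Package: pyrwave
Title: Multiscale Gaussian-Pyramid and Wavelet-Shrinkage Image Denoising
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Benchmarking workbench for classical multiresolution image
    denoising on the 0-255 intensity scale. Implements a Gaussian-pyramid
    denoiser with level-specific filters (bilateral at the finest level,
    median at intermediate levels, Gaussian at the coarsest), orthogonal
    wavelet-shrinkage baselines (Haar, db4, coif4, sym4; soft and hard
    thresholding with the universal threshold), a full-reference image
    quality metric suite (MSE, RMSE, MAE, PSNR, SSIM, pixel-domain VIF,
    Pratt's figure of merit), exact paired statistical comparison (paired t
    and exact Wilcoxon signed-rank by exhaustive sign enumeration), and a
    fully seeded synthetic generator for phantoms and nine noise families
    plus a signal-dependent camera-noise composition.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    png,
    tiff,
    yaml,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
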