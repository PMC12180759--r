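Package: pcadenoise
Title: PCA Denoising of Redundant MRI Data with Noise-Variance Priors
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Sliding-window principal-component-analysis denoising of
    redundant magnetic-resonance data (for example diffusion-weighted
    volumes) with three eigenvalue-classification criteria: the
    Marchenko-Pastur moment-matching criterion (MPPCA), a general criterion
    that compares the mean of the smallest eigenvalues against an a-priori
    noise variance (GPCA), and an eigenvalue threshold derived from the
    Marchenko-Pastur upper bound and the same prior (TPCA).  Includes
    voxelwise noise-variance estimation from repeated b=0 acquisitions,
    overcomplete averaging of overlapping windows, a two-compartment
    crossing-fibre diffusion phantom with spatially correlated noise
    induced by k-space zero-filling or Gaussian smoothing, and evaluation
    utilities (residual maps, quantile-quantile normality, RMSE,
    component-count histograms).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    RNifti,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
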