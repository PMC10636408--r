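Package: fractalbold
Title: Scale-Free Dynamics of Resting-State BOLD Signals
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Voxelwise estimation of power-law scaling (Hurst exponent) in
    resting-state BOLD fMRI time series, with a Welch power-spectral-density
    estimator, detrended fluctuation analysis, wavelet monofractal analysis
    and wavelet-leader multifractal log-cumulants; companion low-frequency
    amplitude (ALFF/fALFF) and local/global connectivity metrics; exact
    circulant-embedding simulation of fractional Gaussian noise volumes and
    multi-group synthetic cohorts; and bootstrapped general-linear-model
    group contrasts with bootstrap ratios, percentile p-values, FDR control
    and Monte-Carlo cluster-size thresholding.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    RNifti,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
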