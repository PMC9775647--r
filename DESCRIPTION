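Package: pixelhe
Title: Pixel-Level Clustering and Local-Entropy Analysis of H&E Histology
Version: 0.1.0
Authors@R: person("pixelhe", "developers", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for pixel-level analysis of hematoxylin-eosin (H&E)
    stained histology images. Computes per-pixel multiscale basic features
    (Gaussian-smoothed intensity and Hessian-eigenvalue texture responses),
    fits a KMeans model on one cohort and transfers it to another to score
    tissue-structure homology via cluster composition ratios, and computes
    per-pixel local Shannon entropy with area-weighted resampling, Welch
    two-sample comparison and per-stage Jensen-Shannon divergence to
    discriminate cancerous from noncancerous regions. Includes a synthetic
    H&E-like cohort generator with ground-truth masks and TNM metadata so
    the whole pipeline is testable without slide scans, plus lossless PNG
    image input/output and TNM to UICC stage mapping.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
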