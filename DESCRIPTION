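Package: fastpca
Title: Fast Approximate PCA and ICA for Calcium-Imaging Movies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Approximate principal component analysis for large
    calcium-imaging movies via biologically informed pixel sampling.
    Pixels are drawn with probabilities proportional to column norms or to
    neighbourhood covariation, NIPALS iteration extracts the top components
    from the sampled sub-matrix, and full-size spatial components are
    reconstructed through the pseudoinverse. Includes Monte-Carlo sample
    size rules with empirical verification of the covariance-error bounds,
    a symmetric fixed-point fastICA stage for spatial or temporal source
    separation of the reduced movie, and a synthetic generator of
    glomerular odor-response movies with ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.0)
Imports:
    MASS,
    stats,
    graphics,
    grDevices,
    utils,
    tiff
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
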