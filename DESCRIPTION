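Package: ramanspc
Title: Superparamagnetic Clustering of Serum Raman Spectra
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Unsupervised discrimination of serum Raman spectra by
    superparamagnetic clustering (SPC). Spectra are baseline-corrected with an
    iterative polynomial fit, Savitzky-Golay smoothed and peak-normalized; a
    mutual nearest-neighbor coupling graph with Gaussian-decaying ferromagnetic
    couplings feeds a q-state Potts model sampled by Swendsen-Wang cluster
    Monte Carlo over a temperature sweep; spin-spin correlations are
    thresholded into data clusters, the magnetic susceptibility locates phase
    transitions, and a sequential procedure extracts the stable natural
    clusters as a temperature hierarchy. Includes a synthetic serum-spectrum
    generator with class-specific band patterns, a principal-component
    cross-check, and an end-to-end pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    igraph,
    signal,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
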