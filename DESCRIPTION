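Package: ftirpls
Title: Chemometric Characterisation of Street Heroin from Mid-Infrared Spectra
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end chemometric workflow for ATR-FTIR pseudo-absorbance
    spectra of street heroin: fingerprint-region selection, four spectral
    pre-treatments (mean centering, autoscaling, standard normal variate and
    the Savitzky-Golay second derivative), Duplex train/test partitioning,
    exploratory principal component analysis with class overlays, NIPALS
    partial least squares regression for purity and PLS discriminant analysis
    for the presence of heroin and ten adulterants or impurities, 10-fold
    cross-validated factor selection, confusion-matrix validation metrics and
    a permutation-based overfitting test. Includes a synthetic mixture-spectrum
    generator emulating the composition structure of real street samples so
    the whole pipeline is testable without measured spectra.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    cluster,
    stats,
    utils
Suggests:
    jsonlite,
    mixOmics,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
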