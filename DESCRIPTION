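Package: nirtransfer
Title: Cross-Brand Calibration Transfer for Near-Infrared Blend Quantification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Quantifies the blending proportion of a component in plant-material
    blends from near-infrared (NIR) absorbance spectra, and transfers such
    calibrations across product brands whose spectra differ in distribution.
    Provides partial least squares regression (SIMPLS) with cross-validated
    latent-variable selection, principal component diagnostics, primal transfer
    component analysis (linear-kernel MMD minimisation), correlation alignment
    (CORAL) recoloring, and model updating by target-domain spiking, together
    with a seeded multi-brand synthetic spectra generator based on Beer-Lambert
    mixing of Gaussian-band endmembers. Spectral datasets are represented as
    SummarizedExperiment objects with a strict wavenumber-grid convention and a
    diffable delimited on-disk format.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    BiocGenerics,
    SummarizedExperiment,
    data.table,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml,
    optparse
Config/testthat/edition: 3
biocViews: Regression, Spectra, Software
RoxygenNote: 7.3.3
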