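Package: noda2d
Title: Generalized Two-Dimensional Correlation Spectroscopy for
    Perturbation-Indexed Spectral Series
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Tools for generalized two-dimensional correlation spectroscopy
    (2D-COS) of perturbation-indexed series of vibrational spectra, such as
    temperature-dependent FTIR-ATR absorbance spectra. Computes dynamic
    spectra against a configurable reference, synchronous and asynchronous
    correlation maps via the discrete Hilbert-Noda transformation matrix,
    detects auto- and cross-peaks, and infers the sequential order of band
    responses from Noda's sign rules. Includes a synthetic band-model
    generator of temperature-series spectra with known ground-truth response
    ordering, CSV import/export of wide-format spectral tables, baseline and
    internal-standard normalization preprocessing, contour plotting, and a
    reproducible end-to-end pipeline driven by YAML configuration.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    graphics,
    grDevices,
    pracma,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
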