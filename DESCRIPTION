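Package: polarcyte
Title: Single-Particle Polarized Light Scattering and Fluorescence Cytometry
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Toolkit for single-particle optical cytometry combining
    division-of-amplitude Stokes polarimetry with a parallel chlorophyll
    fluorescence channel. Provides Mueller matrices of ideal optical
    elements, a forward model of a four-channel polarization-state
    analyzer, least-squares calibration of the instrument matrix and
    inversion of detector voltages to Stokes vectors, transit-pulse
    detection and per-particle feature extraction (I, q, u, v, DOP, F),
    a physical model of the fluorescence yield and collection chain,
    a seeded instrument simulator emulating particle suspensions, and
    LDA/SVM classification with confusion-matrix reporting.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    e1071
Suggests:
    testthat (>= 3.0.0),
    MASS,
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
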