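Package: vesselwall
Title: In-Vivo Mechanical Characterization of the Arterial Wall from
    Intravascular Ultrasound
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to estimate regional stiffness of the coronary arterial
    wall from intravascular ultrasound (IVUS) image sequences. Implements
    image-based cardiac gating, rigid transversal and axial registration,
    speckle denoising and multiresolution variational optical flow to extract
    wall displacement fields; a finite-strain incompressible Neo-Hookean
    mixed finite-element model of a vessel cross-section, including the
    inverse (preload) equilibrium problem that recovers the stress-free
    configuration from the imaged geometry; and a reduced-order unscented
    Kalman filter (ROUKF) that assimilates displacement observations to
    identify a per-region Neo-Hookean stiffness parameter with uncertainty
    intervals. Synthetic-data generators (ring and partitioned-slice meshes,
    in-silico observations, speckled IVUS-like sequences) make the whole
    pipeline testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    Rcpp,
    EBImage,
    jsonlite,
    xml2,
    stats,
    utils,
    parallel,
    tiff,
    png
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
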