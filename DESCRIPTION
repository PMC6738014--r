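Package: cardioscreen
Title: Multiscale In Silico Screening of Drug-Induced Proarrhythmia
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Desk-scale multiscale cardiac drug-safety simulator: Hill-equation
    ion-channel pharmacology drives the O'Hara-Rudy dynamic (ORd) human
    ventricular myocyte model (endocardial, mid-myocardial and epicardial
    variants), monodomain reaction-diffusion propagation on synthetic 1D/2D/3D
    geometries with a Purkinje-style activation scheduler, a forward-computed
    body-surface ECG (infinite-medium and single-surface boundary-element
    models), and proarrhythmia biomarkers (APD90, transmural dispersion of
    repolarization, QTc, JTpeak, early-afterdepolarization and ventricular
    tachycardia flags) for a bundled panel of seven CiPA reference drugs.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    Matrix,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
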