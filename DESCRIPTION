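Package: conformosort
Title: Eigenimage Sorting, Symmetric Reconstruction and Hinge Fitting of
    Multi-Conformer Chaperonin Cryo-EM Particles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A desk-scale single-particle cryo-EM analysis pipeline for
    resolving coexisting conformations of double-ring chaperonin (GroEL-like)
    complexes from side-view projection images.  Provides a pseudo-atomic
    phantom generator for the allosteric T/Rs/Rd/R-open/R-ES state library
    with exactly known hinge kinematics; contrast-transfer-function
    simulation and phase-flip correction, band-pass filtering and
    normalization; eigenimage (principal component) analysis with
    variance-localized component selection, k-means subdivision, junk
    removal and iterative competitive multi-reference alignment; C7
    symmetric reconstruction by direct Fourier inversion with split-half
    Fourier shell correlation; deterministic hinge-constrained rigid-body
    fitting of multi-domain models into density maps; and quantification of
    domain rotations (axis/angle/translation) and intersubunit salt-bridge
    switching patterns used as conformational fingerprints.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    bio3d,
    yaml,
    jsonlite
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
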