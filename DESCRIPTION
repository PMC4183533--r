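Package: dcevox
Title: Intra-Voxel Finite-Element Simulation of Contrast-Agent Kinetics for DCE-MRI
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A two-dimensional finite-element simulator of contrast-agent
    perfusion and diffusion inside an imaging voxel (packed cells, vessels and
    extravascular extracellular space), together with the spoiled gradient
    echo signal model and standard/extended Tofts fitting pipeline. The
    package quantifies how the intra-voxel diffusion coefficient of a
    gadolinium chelate and the scan temporal resolution bias estimates of
    Ktrans, ve and vp obtained with compartmental pharmacokinetic models.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    Rcpp,
    jsonlite,
    minpack.lm,
    methods,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml
Config/testthat/edition: 3
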