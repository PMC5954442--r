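Package: densemble
Title: Bayesian Metainference of Structural Ensembles from Cryo-EM Density Maps
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simultaneous determination of structure and dynamics from cryo-electron
    microscopy density maps by Bayesian metainference. Density maps are represented
    as Gaussian mixture models fitted by a divide-and-conquer weighted EM scheme; a
    structural model predicts the map through an analytic Gaussian forward model; a
    Gaussian noise model with Jeffreys-prior marginalized per-component uncertainties
    scores the agreement between replica-averaged model overlaps and the data;
    multi-replica Langevin sampling with optional well-tempered metadynamics produces
    a thermodynamic ensemble, from which conformational states, their populations and
    per-component noise levels are inferred. Includes MRC2014 map input/output, a GMM
    text dialect, GROMOS-style trajectory clustering, free-energy surfaces over
    collective variables, and a synthetic two-state benchmark.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    graphics,
    grDevices,
    bio3d,
    jsonlite,
    yaml
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
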