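Package: optogap
Title: In Silico Optogenetic Assay of Heterocellular Electrical Coupling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Simulates the OptoGap assay: channelrhodopsin-2 (ChR2) expressing
    non-myocytes (cardiac fibroblasts or hiPSC-derived cardiomyocytes) resistively
    coupled to non-light-sensitive host ventricular cardiomyocytes, where the
    minimal optical irradiance that triggers a host action potential (E_e,th) is a
    quantitative readout of gap-junctional coupling. Provides ionic cell models
    (ten Tusscher 2004 epicardial ventricular myocyte, Paci 2013 ventricular
    hiPSC-CM, MacCannell 2007 active fibroblast, Williams 2013 four-state ChR2
    photocycle), a tandem-cell-unit engine with quiescent equilibration and
    threshold bisection, strength-duration (rheobase/chronaxie) fitting, the
    log-ratio assay sensitivity metric, gapFRAP recovery-curve fitting, and a
    reduced-scale monodomain tissue model with stochastic donor-cell placement
    and depth-dependent illumination.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    minpack.lm,
    stats,
    utils,
    jsonlite,
    rlang
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    optparse,
    yaml
Config/testthat/edition: 3
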