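Package: fibertopo
Title: Topology and Coarse-Grained Simulation of Nucleosome Fibers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Builds base-pair-resolution models of two-start chromatin
    fibers from rigid base-pair step parameters and a left-handed
    nucleosomal superhelix, computes DNA twist, writhe and linking-number
    changes by discretized Gauss double integrals, locates energetically
    optimal regular fibers over a range of linker lengths, samples
    conformational ensembles of nucleosome arrays with Metropolis Monte
    Carlo, and derives experiment-facing observables: internucleosome
    contact statistics, fragment-length distributions of spatially
    correlated DNA breaks, and Kirkwood sedimentation coefficients.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    bio3d,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
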