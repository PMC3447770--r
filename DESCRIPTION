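Package: microzone
Title: Rate-Coded Cerebellar Microzone Simulation and In-Silico Lesioning
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates a single cerebellar microzone (mossy fibers, climbing
    fibers, granule, Golgi, basket and Purkinje cells, deep cerebellar
    neurons) as a rate-coded point-neuron network with k-winners-take-all
    inhibitory competition, trained on a synthetic eyeblink (puff/buzz)
    conditioning task by a combination of contrastive two-phase error-driven
    learning and conditional-PCA Hebbian learning. Provides in-silico
    neurodegeneration experiments: incremental, permanent removal of cells of
    each type (or size-weighted random removal) from the trained circuit,
    trial-averaged degradation curves of the learned association, linear
    versus logarithmic trend fits, and an inter-stimulus-interval validation
    against a parametric stimulus-trace curve.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    yaml,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
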