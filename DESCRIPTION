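Package: ryrspark
Title: Stochastic Gating of Ryanodine Receptor Clusters and Calcium Spark Timing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Exact stochastic simulation of cardiac ryanodine receptor (RyR2)
    clusters modelled as lattices of tetramers whose two-state subunits are
    coupled within and between channels, with rapid-diffusion dyadic calcium
    feedback. Provides generators for adjoining, oblique, bond-diluted and
    preferential-attachment cluster morphologies, a Gillespie direct-method
    engine with first-passage detection of spontaneous calcium sparks, exact
    master-equation oracles (stationary distributions and mean first-passage
    times) for small clusters, and ensemble sweeps of the mean spark waiting
    time over calcium concentration, coupling strength, bond connectivity and
    cluster compactness.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
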