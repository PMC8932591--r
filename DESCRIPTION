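Package: burstcoast
Title: Burst-and-Coast Fish School Model with Influential-Neighbor Interactions
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Event-driven simulation of schools of rummy-nose tetra
    (Hemigrammus rhodostomus) swimming in an unbounded plane with a
    burst-and-coast (kick-and-glide) locomotion mode. Each fish updates its
    heading at discrete, asynchronous kick onsets by summing empirically
    parameterized attraction and alignment interactions with its k most
    influential neighbors, plus Gaussian heading noise. The package provides
    the pairwise interaction kernels, the influence-based neighbor selection
    rule, the asynchronous event-driven simulator (C++ core with a pure-R
    reference engine), collective-state observables (dispersion, polarization,
    milling index), phase classification, and replicated parameter-sweep
    experiments that map the schooling, milling, swarming, intermittent and
    dispersion phases.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    graphics,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
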