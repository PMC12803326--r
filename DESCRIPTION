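Package: allosinfo
Title: Information Flow in a Stochastic Model of Allosteric Enzyme
    Signaling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Models a minimal allosteric signaling motif -- a single enzyme
    with baseline and allosterically modified conformations that converts a
    substrate into a product sequestered by a downstream protein -- as a
    continuous-time Markov jump process.  Builds the truncated chemical
    master equation generator over the joint state of enzyme conformation,
    downstream occupancy and substrate/product copy numbers, solves for
    stationary and time-dependent distributions under constant or
    square-wave substrate input, and quantifies signaling with the mutual
    information (in nats) between the enzyme's regulatory state and the
    downstream protein's occupancy state.  Every deterministic solver is
    cross-validated against an exact Gillespie stochastic simulation of the
    same reaction network, which doubles as the package's synthetic-data
    generator.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Matrix,
    Rcpp,
    graphics,
    grDevices,
    methods,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
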