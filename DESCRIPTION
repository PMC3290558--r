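Package: mimnet
Title: Mimetic Departure Dynamics on Weighted Social Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Stochastic simulation of collective departures on weighted
    directed social networks spanning the centralized (star) to
    decentralized (equal) continuum. Implements an allelomimetic joining
    model in which each resting individual's per-second departure
    probability is its intrinsic rate plus a mimetic term weighted by its
    affiliation toward the individuals already moving; computes
    eigenvector centrality on received affiliation and the group
    centrality index; reduces Monte-Carlo batches of simulated movements
    to decision variables (number of joiners, joining latencies, central
    versus non-central contrasts); and fits centrality-response curves
    (linear, exponential, logarithmic) with rank-correlation and
    Mann-Whitney contrasts.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    igraph
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
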