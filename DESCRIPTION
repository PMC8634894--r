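Package: actnet
Title: Executable Activity-Network Models of Cell Signalling
Version: 0.1.0
Authors@R: person("actnet", "maintainers", email = "actnet@example.org",
    role = c("aut", "cre"))
Description: Build, simulate and interrogate semi-quantitative activity
    networks of cell signalling, in which every molecular species carries a
    discrete activity level (0-100 by default) and every interaction is a
    single-parameter rate law drawn from three kinetic scenarios.  The
    deterministic event-driven simulator advances one node by one level per
    event, discretely approximating the underlying rate equations, and
    classifies the terminal behaviour (fixed point, small limit cycle, the
    all-zero Null state).  Includes a Boolean-rule-to-activity-network
    translator with slow/fast reaction classes and dual
    expression/post-translational regulation patterns, Monte Carlo cell-fate
    distribution analysis with binomial confidence intervals, single and
    pairwise knockout/overactivation screens, bounded persistence and
    reachability checking with delayed interventions, bundled network motifs,
    a seeded random-network generator, an independent continuous-rate-equation
    oracle, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    xml2,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
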