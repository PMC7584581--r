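Package: connfluct
Title: Structural Determinants of Segregation-Integration Fluctuations on
    the Connectome
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Generative analysis of how connectome geometry, topology, and
    local resting-state-network edges shape dynamic fluctuations between
    segregated and integrated functional-connectivity patterns. Provides
    seeded synthetic structural connectomes; constrained weight-permutation
    surrogates (unconstrained, geometry-, topology-, and jointly constrained
    families plus RSN main/control pairs) with strength-sequence correction;
    delay-coupled Kuramoto phase simulation; Balloon-Windkessel hemodynamic
    conversion to BOLD; tapered sliding-window time-resolved functional
    connectivity; signed modularity, participation and temporal participation
    coefficients; synchrony-matched coupling selection; and nonparametric
    group comparisons of fluctuation magnitudes.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    igraph,
    signal,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
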