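Package: paretonet
Title: Constrained Bi-Objective Optimisation Models of Network Evolution
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Generates complex networks by greedy bi-objective optimisation:
    minimise the total node degree and maximise the total generalised edge
    degree subject to a fixed average shortest path length. One model, swept
    along its path-length constraint, reproduces complete, Delta-distribution,
    compact, community-structure, fractal, regular, small-world, ultra
    small-world, scale-free and random networks. Includes the analytic
    degree-distribution theory (power-law exponent as a function of the
    edge-degree exponents), a similarity-distance revision that makes
    community structure optimal, and the measurement layer needed to verify
    the generated traits: discrete truncated power-law maximum-likelihood
    fitting, box-covering fractal scaling, small-world indices and a regime
    classifier along the path-length spectrum.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    igraph,
    jsonlite,
    Rcpp,
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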