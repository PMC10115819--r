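Package: calfscape
Title: Energy Landscape and Causal Analysis of Antibiotic Effects on Gut Microbial Communities
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for detecting "silent" effects of in-feed antibiotics on
    longitudinal microbiome studies. Implements an extended pairwise
    maximum-entropy (Ising-like) community model with treatment and
    growth-stage covariates, exact probabilities and Gibbs sampling,
    stochastic-approximation maximum-likelihood estimation with repeated-run
    significance, energy-landscape analysis (stable states, basins, gradients),
    signed interaction networks, a response classification of components by
    their treatment and stage couplings, association-rule (market basket)
    screening, and DirectLiNGAM causal discovery with internal-standard
    validation. A synthetic-data module emulates a 12-animal, two-group,
    three-timepoint calf study so the whole pipeline is testable without any
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    igraph,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
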