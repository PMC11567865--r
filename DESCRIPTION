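Package: synaptnet
Title: Multilayer Signed Partial-Correlation Networks for Synaptic
    Proteomics and Neuropathology
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Estimation and analysis of multilayer signed partial-correlation
    networks linking synaptic peptide abundances, protein-protein interactions,
    pathological peptides and cellular pathology. Provides rank-based
    (nonparanormal) Gaussianization, sparse Gaussian graphical model estimation
    by graphical lasso with extended-BIC model selection, signed-network
    topology (strength, closeness, betweenness, expected influence, hubs,
    connectivity, power-law fit), spinglass community detection with negative
    edges, structural-balance triad census, permutation-based two-group network
    comparison with Holm-Bonferroni control, network-informed moderation
    regressions, and a synthetic multilayer data generator with planted ground
    truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    jsonlite,
    Rcpp,
    stats,
    tools,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
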