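Package: phylomrm
Title: Posterior Topology Tests and Multiple Regression on Phylogenetic
    Distance Matrices
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Hypothesis testing against Bayesian posterior tree samples and
    taxon metadata. Pools post-burn-in MCMC tree samples across runs, counts
    the posterior frequency of monophyly and backbone-topology constraints
    (the Bayesian topological test, Pp), builds toponomic, habitat and
    great-circle geographic model distance matrices from a taxon table, and
    fits multiple regression on distance matrices (MRM) of phylogenetic node
    distance on those predictors with matrix-permutation significance tests
    for coefficients and sequential sums of squares. Includes seeded
    simulators for pure-birth trees, posterior tree sets with planted clade
    frequencies, and metadata tables with planted regression structure, so
    every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    dplyr,
    generics,
    geosphere,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    igraph,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
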