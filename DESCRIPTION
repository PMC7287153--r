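Package: cladeshift
Title: Habitat Transitions, Trait Evolution and Modularity on Phylogenies
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Comparative phylogenetic analysis of habitat transitions and
    continuous trait evolution: Mk-model ancestral state reconstruction of a
    discrete habitat character (ER and SYM fits, likelihood-ratio comparison,
    re-rooting marginal probabilities), phylogenetically independent
    contrasts and Brownian-motion evolutionary rates with clade-wise F tests,
    Pagel's lambda phylogenetic signal and lambda-transformed phylogenetic
    generalized least squares, phylogenetic principal components analysis,
    and covariance-ratio modularity testing with a trait-permutation null.
    Includes a synthetic data generator (Yule trees, Mk habitat histories,
    modular multivariate Brownian traits) so the whole pipeline can be
    exercised end to end without external data, and a command-line driver.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    ape (>= 5.0),
    stats,
    utils,
    tools,
    jsonlite,
    optparse
Suggests:
    testthat (>= 3.0.0),
    phytools,
    nlme,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
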