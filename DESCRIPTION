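Package: radsignal
Title: Diagnostics for Ancient Rapid Radiations: Gene-Tree Conflict,
    Phylogenetic Signal and Systematic Bias
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to diagnose why the backbone of an ancient rapid
    radiation resists resolution. Enumerates and classifies all
    constrained resolutions of a clade-level backbone tree, quantifies
    gene-tree conflict (Robinson-Foulds matrices, treespace embedding,
    split frequencies, gene support frequency), computes site
    likelihoods under GTR-family and Mk models with a built-in pruning
    engine, runs approximately unbiased topology tests via multiscale
    RELL bootstrap, profiles phylogenetic informativeness and quartet
    internode signal-and-noise probabilities, ranks sites with
    tree-independent rate proxies (observed variability and character
    agreement) for progressive fast-site removal, screens for
    compositional and lineage-rate biases, and simulates multi-gene
    data under a bush-shaped chronogram with lineage-specific rate
    multipliers and nonstationary AT-shifted base composition.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape (>= 5.0),
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    phytools,
    jsonlite
Config/testthat/edition: 3
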