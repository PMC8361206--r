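Package: stacksdm
Title: Stacked Species Distribution Models with Probit BART on Synthetic Landscapes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end, fully testable workflow for stacked species
    distribution modelling (S-SDM). Generates spatially autocorrelated
    synthetic landscapes, virtual species with known niches, nested
    plot/site surveys and phylogenies with tunable niche conservatism;
    derives the 19 bioclimatic covariates and leaf-area-index composites
    from monthly raster stacks; prepares occurrence data by spatial
    thinning, accessible-area construction and pseudoabsence sampling;
    fits per-species probit Bayesian additive regression tree (BART)
    occurrence models with TSS-maximizing thresholds; stacks predictions
    into assemblage richness and composition under binary, probability
    and probability-ranking-rule procedures; evaluates assemblages with
    richness deviation and change, prediction success, the true skill
    statistic and the Sorensen index; computes SES-MPD phylogenetic
    assemblage structure under a taxon-shuffle null; and compares
    procedures with robust Bayesian correlation and a hierarchical
    Bayesian ANOVA.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    stats,
    utils,
    tools,
    graphics,
    grDevices,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    vegan,
    picante,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
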