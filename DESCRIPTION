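Package: microdrivers
Title: Driver Taxa in Paired Before/After-Treatment Microbiome Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Post-sequencing analysis pipeline for paired case/control (before
    vs after treatment) gut microbiome cohorts built on ASV count tables:
    filtering and TMM normalization, alpha/beta diversity with PCoA/NMDS and
    PERMANOVA, Sloan neutral community model fits with Levins niche breadth
    and C-score null models, SparCC co-occurrence networks with greedy module
    detection, NetShift-style case/control node comparison (NESH, delta
    betweenness) to call driver taxa, indicator species analysis, random
    forest state classification, and negative binomial covariate regression
    with bootstrap significance. Includes a synthetic paired-cohort generator
    with planted differential taxa, correlation modules, and neutrally
    assembled fractions so every stage has a ground-truth recovery test.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    vegan,
    permute,
    igraph,
    minpack.lm,
    randomForest,
    edgeR,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    MASS
Config/testthat/edition: 3
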