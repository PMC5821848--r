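Package: betaregion
Title: Biogeographic Regionalization from Beta-Diversity Turnover
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Delimits biogeographic regions from a grid-cell by species
    presence-absence matrix and attributes them to environmental drivers.
    Computes Simpson turnover dissimilarities (beta-sim), builds consensus
    Ward dendrograms over randomized cell orderings, selects the number of
    regions by a dual criterion (explained-dissimilarity threshold plus the
    mean-silhouette stopping rule), and models region membership with
    multinomial logistic regression ranked by AICc, Akaike weights, percent
    deviance explained and four-group deviance partitioning (climate,
    topography, rivers, vegetation). Includes a synthetic-landscape
    generator (river-delimited lattice blocks, environmental gradients,
    spreading-dye species ranges with river-crossing penalties and climatic
    niche filtering) that provides ground-truth regions for validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    mclust,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    vegan,
    cluster,
    nnet,
    igraph,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
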