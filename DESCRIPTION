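Package: landres
Title: Landscape Resistance Optimization and Connectivity from Individual Genetic Distances
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for individual-based landscape genetics on raster resistance
    surfaces: construction of univariate, buffered-road and multivariate
    resistance surfaces from feature layers; individual pairwise genetic
    distances (proportion-of-shared-alleles Dps and Rousset's a) from
    microsatellite genotypes; least-cost-path cost distances and circuit-theory
    effective resistance and all-to-one current maps; Mantel and partial Mantel
    permutation tests; constrained grid-search optimization of per-feature
    resistance values with a peak/plateau selection rule; maximum-likelihood
    population-effects (MLPE) mixed models ranked by AICc and Akaike weights;
    corridor mapping; and synthetic landscape and genotype generators so the
    whole pipeline is testable without external GIS or genotype downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    igraph,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    vegan,
    MASS,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
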