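Package: riverpopgen
Title: Population Genetics of Metapopulations on Dendritic River Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for studying how the connectivity of dendritic river
    networks and dispersal behaviour shape the genetic diversity of
    metapopulations. Provides a river-network data model with graph-theoretic
    node metrics (upstream distance, accumulated catchment area, betweenness,
    closeness, degree), microsatellite diversity and differentiation
    statistics (rarefied allelic richness, observed and expected
    heterozygosity, F_IS, pairwise Nei F_ST, Garza-Williamson M-ratio, Mantel
    tests), a discrete-time stochastic individual-based metapopulation genetic
    simulator running on the same network graph, a perpendicular-offset
    goodness-of-fit framework comparing simulated to empirical statistics, a
    linear-model layer with collinearity screening, stepwise and all-subsets
    selection and an isolation-by-distance power-term scan, and synthetic
    generators for dendritic networks and island-model genotypes.
License: MIT
Encoding: UTF-8
Imports:
    igraph,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    vegan,
    car,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
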