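Package: aquadyn
Title: Spatio-Temporal Dynamics and Occupancy-Abundance Modeling of Drinking
    Water Microbiomes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Analysis toolkit for spatio-temporal surveys of bacterial
    communities in drinking water distribution systems. Provides rarefied
    alpha and beta diversity (Bray-Curtis, Jaccard, weighted and unweighted
    UniFrac), permutation statistics (PERMANOVA, ANOSIM, beta dispersion,
    Mantel), pipe-network distance-decay analysis, time-lag beta-diversity
    curves, a robust maximal-information-coefficient (MIC) association
    network protocol over rarefaction events with seasonal cluster
    extraction, and maximum-likelihood fitting of interspecific
    occupancy-abundance models (Poisson, Nachman, Hanski-Gyllenberg, power,
    negative binomial) with a month-randomization permutation envelope. A
    synthetic-data generator emulating a 15-month, multi-sector distribution
    system survey lets every stage run without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    ape,
    vegan,
    igraph,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    phyloseq,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
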