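Package: gutenv
Title: Longitudinal Gut Microbiome and Intestinal-Environment Analysis for
    Crossover Designs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis of longitudinal gut microbiome surveys
    with accompanying intestinal-environment chemistry, as collected in
    randomized crossover bed-rest studies. Provides a Dirichlet-multinomial
    synthetic-data generator with planted effects; chromophoric dissolved
    organic matter (DOM) spectral indices (indole ratios, SUVA254, SViA420,
    cDOM, TDLP9 lignin-phenol model) and electrical-conductivity calibration;
    a thirteen-index alpha-diversity suite; Bray-Curtis, Jaccard, Yue-Clayton
    theta and Morisita-Horn dissimilarities plus weighted and unweighted
    UniFrac; PERMANOVA, AMOVA, HOMOVA and Mantel permutation tests with
    Benjamini-Hochberg correction; a four-test differential-taxon battery
    (metastats-style, indicator value, Kruskal-Wallis effect screen,
    abundance-weighted Kolmogorov-Smirnov) with congruency reporting; core
    microbiome ubiquity analysis; and three-matrix variation partitioning with
    step-down variable screening.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    jsonlite,
    stats,
    tools,
    utils,
    vegan,
    yaml
Suggests:
    optparse,
    picante,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
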