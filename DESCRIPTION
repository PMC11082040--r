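Package: standscan
Title: Individual-Tree Detection, Allometry, and Spatial Structure from
    Canopy Height Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for deriving spatially explicit forest inventories from
    drone-photogrammetry canopy height models and for assessing them against
    stem-mapped ground truth. Implements variable-window local-maximum
    treetop detection, marker-controlled watershed crown segmentation,
    breast-height circle fitting and power-law height-diameter allometry
    with prediction-bound filtering, greedy tree-list matching with F-score
    accuracy assessment, stand summaries (trees per hectare, basal area,
    quadratic mean diameter, canopy cover), and individuals-clumps-openings
    spatial structure statistics with one-way ANOVA comparisons. A synthetic
    stand generator emulating four thinning-treatment archetypes makes the
    whole pipeline testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    EBImage,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    MASS,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
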