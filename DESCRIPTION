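Package: menodcn
Title: Differential Correlation Network Analysis for Two-Group Metabolomics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds and analyses differential correlation networks from
    two-group targeted metabolomics panels. Provides a synthetic-data
    generator with planted ground truth, the standard preprocessing chain
    for targeted panels (measurability filtering, half-minimum imputation
    of below-LOD values, covariate residualisation, mean imputation and
    z-normalisation), a Fisher z-based differential correlation statistic
    with a permutation null, network construction with degree, betweenness
    and closeness centrality for hub and bottleneck detection, and
    complementary OPLS-DA biomarker screening with VIP scores, S-plot
    coordinates and cross-validated Q2.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    readr,
    ggplot2,
    igraph,
    jsonlite,
    yaml,
    generics,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
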