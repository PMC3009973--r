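Package: cellmapr
Title: Seed-Based Molecular Map Construction and Network Proximity Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds condition-centred molecular maps by recursive expansion of
    seed proteins over a typed protein-relationship universe, and analyses them
    with the standard toolkit of network medicine: presence analysis of effector
    protein sets, average-minimum ("modified Hausdorff") jump distances between
    protein sets with an empirical all-condition-pairs null distribution and
    percentile significance, geodesic classical multidimensional scaling to two
    dimensions, protein-density grids with peak-region detection, and
    enumeration of direct and k-jump links between seed and effector proteins.
    Includes a synthetic-data module that generates relationship universes,
    seed lists and condition databases with planted topological signal, so the
    whole pipeline is testable without proprietary interaction databases.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    MASS,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
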