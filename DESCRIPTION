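Package: cohortnets
Title: Early Formation of Social Networks in Student Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing the early history of social networks
    observed as weekly directed graphs, such as student cohorts reporting
    whom they worked with. Implements link-turnover statistics (total, new
    and re-established links), cumulative degree and link-weight
    distributions, two-level map-equation community detection on directed
    networks with teleporting random walks, variation-of-information
    distances between partitions, a Kullback-Leibler divergence measure of
    attribute segregation with permutation null models, and alluvial
    diagrams of between-week community flows. Includes a synthetic weekly
    cohort generator with section and gender homophily and tunable link
    persistence, so every stage of the pipeline can be exercised and
    calibrated without survey data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
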