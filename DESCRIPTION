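Package: cephnet
Title: Signed Correlation Networks for Cephalometric Cohorts
Version: 0.1.0
Authors@R: person("cephnet", "maintainers", email = "cephnet@example.org",
    role = c("aut", "cre"))
Description: Builds signed, thresholded Pearson correlation networks over the
    standard set of 21 cephalometric variables and analyses their topology:
    bridge nodes (articulation points), degree hubs, connected components,
    maximal cliques and a lossless power-graph decomposition into clique and
    biclique modules. Includes a stratified cohort pipeline (age groups and
    Wits-appraisal severity classes) and a synthetic-cohort generator with
    planted block correlation structure so every stage can be validated
    against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    xml2,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
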