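Package: kanonet
Title: K-Anonymous Clustering and Masking of Attributed Social Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Privacy-preserving publication of attributed social networks,
    aimed at medical record graphs whose nodes carry quasi-identifiers
    (age, gender, zip code, marital status) and a sensitive attribute
    (diagnosis). Implements graph and attribute distance measures, value
    generalization over user-defined taxonomies, generalization and
    structure information-loss metrics, a greedy k-anonymous clustering
    algorithm with a tunable attribute/structure weight, masked-graph
    construction and export (GraphML and JSON), parameter sweeps over the
    cluster-size floor k and the weight a, a quasi-identifier linkage-attack
    auditor, and seeded synthetic edge generators for benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
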