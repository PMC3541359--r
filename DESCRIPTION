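Package: consenchem
Title: Consensus Clustering of Binary Molecular Fingerprints
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for combining multiple clusterings of chemical structures
    represented as binary fingerprints. Generates cluster ensembles from six
    base clusterers (single, complete, average and weighted-average linkage,
    Ward's method, and a distance-generalised k-means) crossed with six
    distance measures, and combines them with three consensus functions:
    cumulative voting-based aggregation (CVAA) against a fixed Ward reference,
    co-association similarity partitioning (CSPA), and hypergraph minimum-cut
    partitioning (HGPA). Clusterings are scored by their ability to separate
    biologically active from inactive molecules using the per-class F-measure
    and the Quality Partition Index (QPI), macro-averaged over activity
    classes, with paired t-tests for method comparison. Includes a planted
    activity-class fingerprint simulator with a tunable within-class Tanimoto
    diversity dial.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    mclust,
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
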