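Package: fognet
Title: Network-Based Prediction of Non-Muscle Myosin II Contractility Regulators
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Assembles a provenance-tracked protein-protein interactome from
    multiple source edge tables and prioritises candidate regulators of
    non-muscle myosin II contractility with three graph algorithms: a Steiner
    tree 2-approximation over known positive proteins, shortest paths from
    each positive to a target node (the myosin regulatory light chain), and an
    inverse-distance node score. Candidate sets are combined, annotated and
    filtered into a screening table. Also implements the fluorescence image
    statistics used to score contractility phenotypes (coalescence index,
    integrated intensity ratios, normalized mean intensity, contracted-cell
    fractions), and seeded generators for synthetic interactomes with planted
    modules and synthetic cell images, so the whole pipeline is testable
    without external data.
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
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
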