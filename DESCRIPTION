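Package: cliquecavity
Title: Cliques, Topological Cavities, and Persistent Homology of Weighted Brain Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the clique-and-cavity analysis of weighted structural
    brain networks. Implements the weight rank clique filtration with Z2
    persistent homology in dimensions 1-2, recovery of minimal cycle
    representatives at birth density, maximal-clique participation statistics,
    weighted communicability, weighted rich-club coefficients with
    degree-preserving rewired nulls, k-core and s-core decompositions, a
    minimally wired geometric null model, planted-cavity synthetic network
    generators with exact ground truth, and a heuristic for deciding whether a
    topological cavity recurs across repeated scans of the same network.
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
    jsonlite,
    Matrix,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
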