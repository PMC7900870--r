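Package: circaclust
Title: Consensus Category Systems from Pairwise Similarity Judgements
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Derives consensus category systems from psychophysical
    similarity data (free-sorting partitions or sparse same-different
    judgements) by maximizing a Rand-index-style affinity between a hard
    clustering and a soft co-membership matrix (the CIRCA method).
    Includes coordinate-ascent optimization with random restarts and a
    brute-force oracle, cross-validated selection of the number of
    categories, soft-clustering adjusted Rand indices, assignment of
    participant-generated labels to consensus categories, naive and joint
    Bayes association analyses, remove/merge baseline refinement, a
    benchmark harness against k-medoids and spectral clustering, and a
    fully seeded synthetic-data generator.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    cluster,
    kernlab,
    mclust,
    optparse,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
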