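Package: mirmodules
Title: Discovery and Visualization of miRNA-mRNA Functional Modules
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Discovers miRNA-mRNA functional modules in matched expression
    data. Integrates a Spearman correlation matrix with predicted-target
    evidence into a conflict-filtered association matrix, searches it for
    biclusters (modules) with a simulated-annealing seed search followed by
    deterministic expansion into direct (inversely correlated, predicted
    target) and indirect (positively correlated) mRNA arms, quantifies
    cooperativity within miRNA families and genomic clusters against a
    permutation null, annotates modules by hypergeometric enrichment, and
    lays modules out as a bubble plot via an overlap metric and classical
    multidimensional scaling. A synthetic-data generator with planted module
    and cooperativity structure supports end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    dplyr,
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
    utils
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
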