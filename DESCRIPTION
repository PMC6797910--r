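Package: traitpcoc
Title: Site-Level Detection of Convergent Protein Adaptation to Continuous
    Environmental Traits
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Detects amino-acid sites whose evolution tracks repeated shifts
    in a continuous environmental trait (such as habitat temperature or
    log-depth) across a species phylogeny.  The trait is reconstructed on the
    tree under Brownian motion, binarized into candidate convergent scenarios
    at a ladder of trait cutoffs, and every alignment column is scored for a
    convergent amino-acid profile shift under a site-heterogeneous (CAT-style)
    profile-mixture substitution model with a change enforced on transition
    branches.  Per-site posterior probabilities are calibrated with an
    evolutionary-simulation bootstrap yielding adaptive / non-adaptive /
    unresolved calls at a stated confidence, and downstream helpers relate
    calls to protein structural context (flexibility, secondary structure,
    solvent exposure).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape,
    Biostrings,
    car,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo:
    Rcpp
Suggests:
    Matrix,
    optparse,
    phytools,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
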