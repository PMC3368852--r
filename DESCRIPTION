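Package: symvert
Title: Symbiont ITS2 Sequence-Assemblage Analysis for Vertically
    Transmitting Corals
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for comparing Symbiodiniaceae ITS2 sequence assemblages
    between coral parent colonies and their eggs from clone-library data.
    Implements clone-library screening (recovery and pseudogene rules),
    pairwise Hamming distances with gaps as a fifth state, statistical
    parsimony haplotype networks with a confidence-based connection limit,
    the Renkonen/Wolda percent similarity index, two-group distance AMOVA
    with permutation tests, nested multifactor distance-based variance
    partitioning (PERMANOVA-style), hierarchical diploid AMOVA on host
    nuclear genotypes with exact tests of non-differentiation,
    environmental site summaries, and a synthetic clone-library generator
    for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    readr,
    stringr,
    ggplot2,
    generics,
    igraph,
    jsonlite,
    Biostrings,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
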