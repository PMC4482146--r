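Package: seedforage
Title: Partitioning Scatter-Hoarder Foraging Behavior Among Seed Traits and Tree Phylogeny
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Phylogenetic comparative analysis of scatter-hoarder foraging
    investments in tree seeds. Implements Moran's I and Abouheif tests of
    phylogenetic signal with permutation nulls, phylogenetic eigenvector
    regression (PVR) with partial-regression variance partitioning,
    phylogenetic principal component analysis (pPCA) with global and local
    axes, permutation-inference multiple regression, a Kendall's W
    concordance test for distance matrices, and simulators (Yule trees,
    Brownian and lambda-attenuated traits, behavioral responses) that
    exercise the whole pipeline end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    withr
Config/testthat/edition: 3
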