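Package: driftlattice
Title: Neutral Genetic Drift on Spatially Constrained Mating Lattices
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Forward-in-time simulation of neutral two-allele genetic drift in
    diploid populations arranged on periodic lattices, with four mate-choice
    topologies: von Neumann (4-neighbour), hexagonal (6-neighbour), Moore
    (8-neighbour) and panmictic. Populations are iterated by synchronous
    generations of random mate choice and Mendelian gamete sampling until
    allelic fixation. Includes replicate experiment runners for fixation-time
    distributions and their inverse-Gaussian fits, mean-fixation-time versus
    population-size slopes and effective-size ratios, heterozygosity decay and
    inbreeding statistics, connected-component analysis of homozygous genotype
    clusters on the periodic lattice, and a command-line interface for seeded,
    reproducible runs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    purrr,
    ggplot2,
    generics,
    igraph,
    jsonlite,
    optparse,
    yaml,
    rlang,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
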