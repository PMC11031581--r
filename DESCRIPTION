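Package: cannfor
Title: Optimal Foraging Theory for Filial Cannibalism in Territorial Predators
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Discrete-time cohort model of a territorial, filially cannibalistic
    predator (the damsel bug Nabis pseudoferus) with a prey-preference-dependent
    Holling type II functional and numerical response. Runs the single-female
    territory recursion, computes two fitness functionals - life reproductive
    success (X) and reproductive-season growth rate (Z, via a renewal recursion
    over the descendants tree) - and grid-optimises both over conspecific and
    heterospecific prey-preference space. Includes laboratory-estimated and
    illustrative parameter sets, a seeded random-parameter generator, and a
    stochastic individual-based oracle for validating the deterministic
    recursion.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    ggplot2,
    rlang,
    generics,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
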