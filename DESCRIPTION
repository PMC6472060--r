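Package: ragesim
Title: Simulation of Genome Editing and Carrier Selection Against
    Polygenic Deleterious Load in Animal Breeding Programs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Forward-in-time stochastic simulation of a closed animal
    breeding population carrying polygenic deleterious load under
    simultaneous natural (viability) selection and truncation selection
    on true breeding values. Implements removal of alleles by genome
    editing (RAGE) in selected sires under five variant-prioritization
    strategies, and selection against carrier sires under three
    load-scoring strategies, together with deleterious-variant discovery
    with false positives, editing mortality, a Wright-Fisher founder
    generator with a realistic allele-frequency spectrum, a scenario
    grid runner with paired replicate seeding, and the evaluation
    metrics (fitness change versus baseline, relative change in genetic
    gain, distinct variants edited, load decomposition).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    data.table,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    vcfR,
    optparse,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
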