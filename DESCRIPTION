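Package: protocell
Title: Stochastic Growth and Division of Catalytic Protocells
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulates protocells: semipermeable lipid vesicles hosting a
    Kauffman-style catalytic polymer chemistry (cleavage and condensation via
    transient catalyst-substrate complexes) evolved with an extended Gillespie
    stochastic simulation algorithm in a time-varying internal volume. The
    membrane grows in proportion to the copy numbers of container-coupled
    catalysts and the vesicle divides at a lipid-count threshold, partitioning
    its contents stochastically between two daughters. Tools are provided to
    generate and validate artificial chemistries, detect strongly connected
    components and RAF (reflexively autocatalytic, food-generated) sets with
    their irreducible subsets, run multi-generation lineages with
    synchronization and dilution diagnostics, model transmembrane transport by
    Fick's law, and iterate deterministic population maps for competing
    protocell subpopulations.
License: MIT
Encoding: UTF-8
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
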