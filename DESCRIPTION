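Package: fluxblock
Title: Blocked-Metabolite Analysis of Constraint-Based Metabolic Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects metabolites whose de-novo biosynthesis is abolished by
    gene knockouts or by cofactor (e.g. folate) deficiency in constraint-based
    metabolic models, and ranks gene defects by the similarity of their
    blocked-metabolite footprint to a reference deficiency footprint.
    Producibility is measured as the maximal flux of a per-metabolite
    irreversible sink reaction under steady-state flux balance; this catches
    cycle-regenerated cofactors that the classical flux-sum definition of
    blockedness misses. Includes SBML Level 3 FBC import/export, growth-medium
    application, gene-protein-reaction rule evaluation, flux variability
    analysis, Jaccard and generalized Jaccard footprint comparison, a
    synthetic-network fixture generator, and an exact elementary-flux-mode
    producibility oracle for verification on small networks.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    Matrix,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    xml2
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
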