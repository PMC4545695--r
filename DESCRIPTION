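Package: netreduce
Title: Reduction of Stoichiometric Metabolic Network Models to Core Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Automated reduction of constraint-based (stoichiometric) metabolic
    network models to meaningful core models. Given a genome-scale or smaller
    model plus a specification of protected metabolites, reactions and
    phenotypes (linear flux scenarios), the package iteratively prunes
    dispensable reactions using flux variability analysis while provably
    preserving the protected functionality, then optionally applies loss-free
    compression that lumps enzyme subsets (reactions with proportional
    steady-state fluxes) into overall reactions and derives a condensed
    biomass synthesis reaction consistent with the full model. Includes
    readers and writers for SBML (Level 3 + fbc) and a plain TSV model
    format, a YAML protection-specification format, flux balance and flux
    variability analysis on a built-in bounded-variable simplex solver, toy
    network builders and a seeded random-network generator for validation,
    and tidy (tibble) accessors with ggplot2 plotting for all tabular
    results.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    rlang,
    stats,
    tibble,
    utils,
    xml2,
    yaml
Suggests:
    boot,
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
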