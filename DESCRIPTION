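Package: acetoflux
Title: Stoichiometric Yield Analysis for Acetyl-CoA-Derived Bioproducts
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Curated small-scale stoichiometric models of Escherichia coli
    central carbon metabolism coupled to engineered product pathways
    (poly(3-hydroxybutyrate), 3-hydroxypropionate, phloroglucinol) for
    comparing glucose, ethanol and acetate as fermentation feedstocks.
    Computes maximum theoretical product yields by exact linear programming,
    ATP yields under complete substrate oxidation with configurable P/O
    ratios, carbon recovery and net overall stoichiometry; validates every
    reaction by exact carbon and degree-of-reduction balance. Also provides
    fermentation time-course yield arithmetic (consumption, titer, yield,
    polymer content, percent of theoretical), fold-change analysis of
    targeted metabolite panels, and seeded synthetic-data generators
    (logistic growth with Luedeking-Piret product kinetics; lognormal
    replicate panels) so the full pipeline is testable with known ground
    truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
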