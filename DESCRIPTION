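Package: syntherm
Title: Thermodynamics of Competing Acetate-Degrading Methanogenic Pathways
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Bioenergetic analysis of a defined thermophilic consortium in
    which acetate is converted to methane either directly (aceticlastic
    methanogenesis) or syntrophically (acetate oxidation coupled to
    hydrogenotrophic methanogenesis). Provides carbonate-system speciation
    for closed serum vials, standard and in-situ Gibbs free energy changes
    of the three catabolic reactions from metabolite time courses,
    feasibility thresholds and hydrogen partial-pressure counterfactuals,
    a synthetic batch-culture generator with known ground truth, and a tidy
    analysis pipeline producing per-day free-energy series, log-phase
    summaries, methanogenic rates, and normalized 16S abundances.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
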