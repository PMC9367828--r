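Package: nanofate
Title: Fate of Citrate-Coated Silver Nanoparticles in High-Ammonia Wastewater
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for modelling the colloidal and chemical fate of
    citrate-coated silver nanoparticles in high-ammonia-nitrogen wastewater
    and anammox sludge. Includes a tableau-style aqueous equilibrium
    speciation solver with Davies activity corrections (medium speciation and
    dissolved-silver chloro/ammine distributions), sphere-sphere DLVO
    interaction-energy profiles with a retarded van der Waals term and energy
    barrier extraction, aggregation-rate statistics on hydrodynamic-size time
    series, a suspended/dissolved/settled silver mass balance, and seeded
    generators of instrument-like synthetic datasets for testing every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    tibble,
    tidyr,
    tools,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
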