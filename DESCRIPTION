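Package: casarabe
Title: Population Models for the Casarabe Culture of the Llanos de Moxos
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reusable pipeline for constraining the population size of the
    pre-Columbian Casarabe Culture of Amazonian Bolivia from three directions:
    architectural energetics (the workforce implied by the earthen mounds and
    the causeway-canal network, using the Pandolf load-carriage equation for
    transport rates), maximum carrying capacity (per-capita land requirements
    for swidden maize cultivation and sustainable fuelwood extraction under
    three land-allocation scenarios), and a household-level agent-based
    settlement simulator with demography, resource-limited subsistence,
    migration and settlement founding on a gridded forest-savanna landscape.
    Includes a seeded procedural generator of synthetic landscapes and
    reference site sets, Latin hypercube experiment designs over the
    simulator's parameter space, and a spatial-configuration distance metric
    comparing simulated settlement patterns to reference mound locations.
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
    lhs,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
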