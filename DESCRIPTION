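Package: reefherb
Title: Herbivore Functional Groups and Coral Reef Bistability
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Deterministic simulation model of a coral reef benthos (coral,
    turf algae, macroalgae) coupled to three herbivorous fish functional
    groups (grazers, browsers, generalists) through Holling type II
    herbivory and a shared, coral-dependent carrying capacity. Provides
    scenario generators for factorial initial-condition grids, steady-state
    integration and outcome classification, and bistability and hysteresis
    analyses over fishing pressure, for studying reef resilience and
    alternative stable states under overfishing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    ggplot2,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
NeedsCompilation: yes
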