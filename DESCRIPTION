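Package: breathsim
Title: Lumped-Parameter Simulation of Infant Breathing Mechanics and
    Carbon Dioxide Rebreathing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An in-silico mechanical infant breathing model: a compliant
    lung with prescribed tidal excursion breathing through configurable
    airflow resistances (laminar tube, sharp-edged orifices) and an
    optional bedding gas-storage compartment, with breath-by-breath
    carbon dioxide and oxygen transport, equilibrium detection, and a
    work-of-breathing analyzer based on the negative-pressure-side area
    of the pressure-volume loop. Includes a harness reproducing three
    test series that separate the airflow-resistance and CO2-rebreathing
    suffocation mechanisms, an analytic per-breath recurrence used as an
    oracle, and synthetic pressure-volume fixture generators with
    closed-form expected work.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    tibble,
    tidyr,
    yaml
Suggests:
    jsonlite,
    knitr,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
VignetteBuilder: knitr
Config/testthat/edition: 3
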