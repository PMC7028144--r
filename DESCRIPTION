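Package: rootkin
Title: Kinematic and Cellular Analysis of Plant Root Growth Zones
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Dissects primary root growth into cell production and cell
    elongation. Estimates velocity, cell-flux and relative elemental growth
    rate (REGR) profiles from toner-particle displacement data, locates the
    meristem and growth-zone boundaries with the 95%-of-plateau rule, and
    derives cell production, cell-cycle duration and elongation-zone transit
    time. Segments ordered cortical cell-length profiles into meristem,
    rapid-elongation and mature zones using the cell-length doubling rule,
    classifies flow-cytometry DNA-content intensities into ploidy classes
    (2C-32C), and provides the group-comparison statistics (Welch t, one-way
    ANOVA with Tukey HSD) used in such studies. A steady-state growth-zone
    simulator with configurable measurement noise supplies ground-truth data
    for validation and power analysis.
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
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
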