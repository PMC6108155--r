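Package: mmspar
Title: Multi-Modal Two-Step Floating Catchment Area Accessibility with
    Spatial Access Ratios
Version: 0.1.0
Authors@R:
    person("mmspar", "developers", email = "mmspar@example.org",
           role = c("aut", "cre"))
Description: Implements the enhanced two-step floating catchment area
    (E2SFCA) model of spatial accessibility to health care under multiple
    transportation modes, with Gaussian distance-decay impedance evaluated
    on travel-time sub-zones. Produces mode-specific and integrated spatial
    access indices (SPAI) and their normalized spatial access ratios (SPAR),
    the classic single-mode E2SFCA baseline, an impedance-coefficient
    sensitivity battery (coefficient grids, descriptive statistics, one-way
    ANOVA hypothesis tests), and a reproducible synthetic-scene generator
    for supply sites, mode-split demand, and per-mode origin-destination
    travel-time matrices.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
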