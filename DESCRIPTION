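Package: windcape
Title: Windthrow Density Modelling from Convective Available Potential Energy
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Links convective available potential energy (CAPE) to the
    density of large wind-driven forest disturbances (windthrows).
    Computes nondilute near-surface-parcel CAPE from atmospheric
    profiles by a discrete positive-buoyancy sum, fits a non-parametric
    equal-count binned look-up table of windthrow density against CAPE
    with bootstrap uncertainty, scales Earth-system-model futures onto a
    reanalysis baseline by fractional delta change, and projects
    storm-favorable area and windthrow-density increases. Includes
    spherical-grid bookkeeping, synthetic climate-field and
    inhomogeneous-Poisson event generators for end-to-end testing, and
    plain-text readers and writers for all inputs and results.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
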