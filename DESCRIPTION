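Package: careaccess
Title: Distance-Based Accessibility Indicators for Community Care Services
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Profiles the spatial accessibility of community health and
    long-term-care services from user and provider point tables. Matches each
    service user to the nearest same-area provider, bins the nearest-distance
    distribution into fixed-width frequency curves, fits continuous piecewise
    linear (joinpoint) models with permutation or BIC model selection, and
    derives two accessibility indicators per administrative area: the profit
    willing distance (PWD, first significant downturn of the curve) and the
    tolerance limited distance (TLD, first significant upturn). Areas are
    classified by indicator presence, combined with case-to-provider service
    densities, and ranked for resource-allocation priority. Includes WHODAS
    2.0 simple scoring and needs stratification, and seeded synthetic-data
    generators for every input so the whole pipeline is testable without
    restricted registry data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    geosphere
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
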