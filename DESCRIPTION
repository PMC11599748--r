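Package: marshstock
Title: Spatially Explicit Mapping of Tidal-Marsh Soil Organic Carbon Stocks
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: A depth-explicit pipeline for mapping soil organic carbon (SOC)
    stocks in tidal marshes. Models organic carbon density as a function of
    soil depth and landscape covariates with a random forest, validates it
    with nearest-neighbour distance-matched spatial cross-validation, masks
    predictions by a dissimilarity-based area of applicability, calibrates a
    per-pixel expected error from cross-validation residuals, integrates
    standard-depth predictions to layer stocks by the trapezoid rule, and
    aggregates stocks to cells, regions and global totals. Includes a
    synthetic-landscape generator emulating geographically clustered,
    depth-stratified soil-core campaigns so the full pipeline can be
    exercised and tested without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ranger,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
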