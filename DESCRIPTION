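Package: dyadhulls
Title: Time-Local Convex Hull Space Use and Dyadic Interaction Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing satellite-telemetry trajectories of
    territorial central-place foragers such as red and Arctic foxes.
    Implements trajectory cleaning (variogram residency screening and a
    one-sided Hampel excursion filter on Tukey-transformed centroid
    distances), time-local convex hull (T-LoCoH) utilization
    distributions with time-use metrics (number of separate visits and
    mean locations per visit), home-range overlap indices, Minta's
    spatio-temporal interaction coefficients for neighbouring dyads,
    habitat composition of core-use isopleths against a categorical
    landcover raster, resampling tests, and a seeded synthetic-data
    generator that emulates den-centred fox movement so the whole
    pipeline is testable without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    jsonlite,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0),
    geosphere
Config/testthat/edition: 3
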