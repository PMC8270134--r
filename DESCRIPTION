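Package: rewildr
Title: Spatially Explicit Monitoring of Rewilding Progress
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A pipeline for monitoring reintroduction (trophic rewilding)
    projects from a habitat map and wildlife-tracking points. Estimates
    species ranges as 95% kernel-density volume contours, builds
    pseudo-absence resource-selection models from fractional habitat cover,
    predicts per-cell probability of presence, and derives maps and area
    tables of realized and potential occupancy, faunal complexity, and an
    ecological-integrity score before versus after reintroduction. Includes
    a two-step land-cover mapping stage (fine-resolution pixel classifier
    plus coarse fractional-cover regressor) and seeded synthetic-data
    generators for landscapes, imagery and tracking data so every stage can
    be exercised without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    mgcv,
    nnet,
    randomForest,
    jsonlite,
    yaml,
    withr
Suggests:
    testthat (>= 3.0.0),
    MASS,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
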