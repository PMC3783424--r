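Package: aslforage
Title: Movement, Oceanography and Whisker-Isotope Analysis for
    Central-Place Foraging Sea Lions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An analysis pipeline for at-sea movement of central-place
    foraging pinnipeds tracked with ARGOS-linked CTD tags: location-class
    filtering and McConnell speed filtering, continuous-time correlated
    random walk interpolation, foraging-trip segmentation, first-passage-time
    area-restricted-search analysis, Brownian-bridge utilization
    distributions, CTD-derived water-column structure (potential density,
    mixed layer depth, thermocline intensity, upwelled-water classification),
    Cox proportional-hazards models of habitat residency, and seasonal ARIMA
    models of whisker stable-isotope series. Includes synthetic-data
    generators that emulate every input so the full pipeline is testable
    end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    survival,
    geosphere,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
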