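Package: groundtruthr
Title: Simulation and Accuracy Analysis of Modified Ground-Truthing for
    Food Environment Validation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for evaluating the accuracy and field cost of validating
    commercial food-store listings against on-site ground-truthing in town
    and rural study areas. Generates synthetic foodscapes (road networks,
    store censuses, and error-laden commercial listings), matches listing
    records to field-verified stores, identifies central commercial clusters
    as buffer unions around listed store locations, simulates a modified
    validation protocol that canvasses only cluster interiors under an
    open-or-closed assumption for out-of-cluster records, and computes
    positive predictive value, sensitivity, and mileage/trip/dollar cost
    reports. Includes a deterministic three-site example dataset and a
    pipeline runner with delimited-text and GeoJSON input/output.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    igraph,
    jsonlite,
    rlang,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
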