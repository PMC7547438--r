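Package: hipwait
Title: Surgical Demand and Time to Hip Fracture Surgery from
    Interval-Censored Discharge Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying how day-to-day variation in surgical demand
    relates to time to hip fracture surgery in hospital discharge data.
    Provides a discrete-event generator of synthetic discharge abstracts with
    capacity-limited surgical queues, care-episode assembly from transfer
    abstracts, a queueing-based clearance-time demand metric with a four-level
    classification, a log-normal accelerated failure time model for
    interval-censored day-grid times with hospital random effects estimated by
    adaptive Gauss-Hermite quadrature and cluster-robust sandwich errors, a
    Turnbull self-consistency estimator of the cumulative probability of
    surgery, and reporting helpers that assemble descriptive and inferential
    tables from the fitted models.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    pracma,
    purrr,
    rlang,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    survival,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
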