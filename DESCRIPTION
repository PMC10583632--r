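Package: mausim
Title: Discrete-Time Simulation of Bed Occupancy in Municipal Acute Units
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for capacity planning in small admission-avoidance
    inpatient units (municipal acute units, MAUs). Implements a
    discrete-time stochastic simulation of daily bed occupancy driven by a
    linear-regression admission sub-model (weekday and month effects, Poisson
    arrivals) and a logistic discharge sub-model (weekday effect), with a
    capacity constraint, a 50-50 rule for same-day reuse of freed beds,
    unit-merging and bed-reduction scenario experiments, and unconstrained
    demand estimation. Includes the Erlang loss model with a bisection
    inverse for triangulating loads against observed occupancies, record
    cleaning and midnight-census utilities, regression calibration from
    admission records, and a synthetic-record generator for end-to-end
    testing. All user-facing functions take and return tidy data frames.
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
    lubridate,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
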