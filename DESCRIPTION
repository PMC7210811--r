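Package: thermalgerm
Title: Thermal-Time Analysis of Seed Germination After Cold Stratification
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for thermal-time (degree-day) analysis of seed
    germination time-courses. Builds cumulative germination curves on a
    filled-seed basis, interpolates percentile germination times,
    estimates the base temperature (Tb) as the mean x-intercept of
    per-percentile germination-rate regressions over the sub-optimal
    temperature range, and derives thermal-time constants (theta) from
    regressions constrained through Tb. Includes quasi-binomial and
    quasi-Poisson inference on germination proportions and Tb, cold-day
    counting of soil-temperature logger series under IPCC RCP warming
    increments, and a synthetic-data generator for germination
    experiments and soil-temperature series with known ground truth.
    Motivated by dormancy-release studies of mountain species such as
    Gentiana lutea, whose seeds require prolonged cold stratification.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
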