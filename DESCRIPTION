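Package: irmsim
Title: Dynamic Polygenic Insecticide Resistance Management Simulation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Simulates the evolution of polygenic insecticide resistance in
    mosquito populations under operational vector-control strategies.
    Resistance is tracked as a normally distributed polygenic resistance
    score whose response to selection follows the sex-specific Breeder's
    equation, with selection differentials recomputed every generation from
    the current resistance level and insecticide efficacy. Two selection
    mechanisms are provided (truncation and probabilistic), the
    probabilistic branch extending to multiple gonotrophic cycles with
    natural mortality, household-level coverage and mosquito age profiles.
    A strategy engine schedules monotherapy sequences and rotations,
    mixtures, micro-mosaics and ITN+IRS combinations under bioassay-survival
    withdrawal and return thresholds, and an experiments layer supports
    exposure-factor calibration, Latin-hypercube strategy comparisons and
    sensitivity analyses.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    lhs,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
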