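Package: wheeltracker
Title: Simulation and Analysis of Voluntary Wheel-Running Activity Logs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A software twin of a low-cost Hall-sensor tracker for voluntary
    wheel running in rodent home cages. Simulates ground-truth wheel
    rotations (deterministic constant-speed validation runs and a stochastic
    nocturnal virtual mouse), emulates the sensor and microcontroller
    acquisition chain into timestamped cumulative-count serial logs, parses
    and quality-controls those logs (wheel jams, counter resets, dead
    sensors), derives distance, velocity and light/dark activity summaries,
    and tests paired before/after designs with a sign-flip permutation test
    backed by an exact enumeration oracle.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    tibble,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
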