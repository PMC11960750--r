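Package: herdmap
Title: Mapping Space-Use and Grazing Activity of Collared Livestock
Version: 0.1.0
Authors@R:
    person("Herdmap", "Maintainers", email = "maintainers@herdmap.invalid",
           role = c("aut", "cre"))
Description: Tools for turning low-frequency virtual-fencing collar telemetry
    (GPS fixes, 30-minute activity-index counts, collar temperature) into
    spatiotemporal maps of livestock space-use and grazing activity. Implements
    two utilization-distribution estimators on a square grid: a dwell-time
    cell-count method and a Brownian Bridge Movement Model (BBMM) extended to
    spread activity-index mass along estimated movement paths. Provides
    core/full-range volume isopleths, Bhattacharyya-coefficient comparisons of
    normalized distributions, activity-index validation against direct grazing
    observations, intensity thresholding, diurnal and fortnightly activity
    profiles, temperature surfaces, and a seeded synthetic-herd simulator with
    ground truth for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
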