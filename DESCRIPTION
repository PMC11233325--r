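Package: zeitact
Title: Rest-Activity Rhythm Analysis for Tracked Fish Locomotion
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies circadian rest-activity rhythms from positional
    tracking of fish (and other animals) recorded under light:dark cycles.
    Computes per-frame swimming speed, detects rest bouts by a
    velocity-threshold-and-minimum-duration rule, bins locomotion and rest
    into zeitgeber-time hourly profiles, and derives diurnality (activity
    change ratio) and crepuscularity indices, with the associated
    statistical comparisons (one-way and split-plot ANOVA with Sidak post
    hoc contrasts, paired day/night tests, cross-stage regression). Includes
    a two-state semi-Markov locomotor simulator with closed-form ground
    truth for validation, and parsers for video-tracker positional exports
    and manually scored ethogram event tables.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
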