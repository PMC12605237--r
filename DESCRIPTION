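Package: dyadtrack
Title: Dyadic Social Event Detection and Longitudinal Incubation Analysis
    for Open-Field Mouse Trajectories
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for longitudinal phenotyping of social behavior in pairs
    of freely interacting mice tracked in a square open field. Provides a
    seeded agent-based generator of single- and two-mouse trajectory
    cohorts with programmable treatment effects, deterministic geometric
    classifiers for static and dynamic dyadic events (contacts by subtype,
    approaches, breaks, follows, movement bouts, rearing, center-zone
    occupancy), per-session behavioral measures, and an inference layer
    based on Z-score standardization to the control-group baseline,
    early/late phase composites, combined social and motor scores, mixed
    repeated-measures ANOVA with Greenhouse-Geisser correction, Tukey and
    Fisher LSD post-hoc comparisons, and linear regressions for
    early-to-late prediction analyses.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    stats,
    utils,
    tools,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
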