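Package: homingtraj
Title: Trajectory-Based Classification of Homing Strategies in Displaced Fish
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for detecting path integration and other homing strategies
    in displacement experiments with shell-dwelling cichlids. Observed homing
    trajectories are scored against model trajectories for path integration,
    allothetic place cues and route recapitulation by pointwise Euclidean
    distance between 1000 arc-length-interpolated points (modified Akima),
    tested against a null of 10,000 random straight trajectories, and labelled
    by a uniform-SD threshold rule. Includes axial circular statistics with a
    von Mises mixture model family selected by AIC, orientation-angle
    extraction with the 10-degree segment-accretion rule, bootstrap one-sample
    tests against model expectations, a multinomial strategy-choice model with
    cluster-robust errors, and a synthetic-cohort generator with known
    ground-truth strategies so the entire pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    nnet,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
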