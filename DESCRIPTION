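Package: flydom
Title: Dominance Onset and Reversal Analysis for Dyadic Fly Contests
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for identifying the establishment and reversals of social
    dominance in dyadic contests between male flies from tracked trajectories
    and ethogram event tables. Implements the pursue-to-climb diagnostic
    criterion (one male consistently pursues until the retreating male climbs
    the arena wall), kinematic bout detectors for pursuit, chase, wall climb
    and lunge, peri-event alignment of aggressive acts to dominance onset with
    exact paired Wilcoxon signed-rank comparisons, dominance-outcome
    contingency analyses, and an agent-based contest simulator that generates
    trajectories and event streams with known ground-truth dominance
    timelines for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
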