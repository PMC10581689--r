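Package: hybridarm
Title: Movement-Based Control of a Simulated Transhumeral Prosthesis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation pipeline for goal-aware, movement-based control of a
    transhumeral prosthesis. Provides a 7 degree-of-freedom arm kinematic model
    with morphology remapping and mirroring, generation of 'plausible' targets by
    rejection sampling of joint ranges of motion under workspace filters and of
    'possible' targets from a Growing Neural Gas fitted to visited arm postures,
    a neural-network predictor of the five distal joint angles from shoulder
    angles plus goal location (trained on natural movements with the
    hand-location-as-target substitution), a deterministic synergy-based movement
    generator producing 90 Hz pick-and-place sessions, and closed-loop evaluation
    of hybrid-arm control with target-zone validation, trial-cleaning filters and
    the movement-time / success-rate / shoulder spread-volume metrics.
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
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    cluster,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
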