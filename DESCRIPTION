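Package: squarestask
Title: Closed-Loop Simulation and Analysis of the Squares Judgement-of-Agency Task
Version: 0.1.0
Authors@R: person("Squares", "Task Maintainers", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Simulates the Squares judgement-of-agency task, in which eight
    on-screen squares are driven by a shared mouse input under a 2x2
    manipulation of angular variability (width of the jitter distribution)
    and volatility (how often that width changes within a trial), and
    implements the complete analysis pipeline for it: binocular eye-trace
    cleaning (blink interpolation, Hanning smoothing, binocular merging,
    frame alignment, poor-signal exclusion), cursor kinematics and
    turn/policy classification, a biased-nearest-object assignment of the
    looked-at square, a per-frame behavioural prediction-error proxy with
    trial averages and slopes, event-related prediction error around
    hypothesis switches, and linear mixed-model effect tables with
    Bonferroni post-hoc contrasts. Seeded synthetic participants (policy
    driven mouse traces, a threshold-switching gaze agent, eye-tracker
    artifact injection, agency judgements) make every stage testable
    without human data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    lme4,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
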