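Package: shufflespeller
Title: Simulation and Decoding Toolkit for a Shuffle-Speller Brain-Computer
    Typing Interface
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements the decision core and evaluation protocol of a
    four-box shuffle-speller typing interface for people with severe
    speech and physical impairment, driven either by steady-state visual
    evoked potentials (SSVEP) or by eye tracking.  Provides seeded
    generators for SSVEP-like EEG and gaze trails, canonical-correlation
    feature extraction against harmonic reference banks, per-target
    kernel-density likelihood models with leave-one-out confusion
    estimation, Nykopp information-transfer-rate (channel capacity)
    computation with adaptive trial-length selection, an
    information-optimal alphabet partitioner with recursive Bayesian
    character selection, copy-spelling session simulators for
    dwell-based and shuffle-based conditions, and the accuracy and
    characters-per-minute metrics used to compare them.
License: MIT + file LICENSE
Encoding: UTF-8
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
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
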