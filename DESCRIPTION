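Package: arenalab
Title: A Headless Virtual Laboratory for Comparative-Cognition Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A deterministic, discrete-time arena simulator for building
    comparative-cognition-style experiments on computational agents. Provides a
    YAML task-configuration format with randomisation tokens, overlap detection
    and precedence-based object placement; a simple rigid-body physics step with
    nine discrete agent actions; reward and health accounting with valenced
    objects, zones, dispensers, buttons and sign boards; raycast and ray-grid
    camera observation models with lights-out masking; an episodic reset/step
    interface with per-step logging; a battery of baseline agents (random-action,
    heuristic raycast navigators, scripted oracles); procedural task generation
    including foraging and operant-chamber tasks with curricula; and a batch
    evaluation harness producing tidy result tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    yaml,
    jsonlite,
    tibble,
    dplyr,
    purrr,
    tidyr,
    ggplot2,
    rlang,
    generics,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
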