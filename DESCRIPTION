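Package: audiomemory
Title: Simulation and Permutation-Based Analysis of a Spatialized
    Sound-Pairing Memory Task
Version: 0.1.0
Authors@R:
    person("ARENA", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for studying spatial working memory with an audio
    adaptation of the card game "Memory" played on a 5x5 speaker board.
    Provides a rule-complete simulator of the pairing game (4-pair and
    12-pair difficulty conditions), three behavioral indices computed from
    touch-event logs (Score, Number of Attempts, Audio-Anchor), a
    parameterized synthetic-agent cohort generator emulating a two-group by
    two-condition within-subject design, and a from-scratch permutation
    inference cascade: permutation Welch t-tests with Cohen's d, two-factor
    mixed-design permutation ANOVA with partial eta squared, and a
    distance-based multivariate permutation test (pseudo-F partitioning)
    with a covariate. A small command-line pipeline ties simulation,
    scoring and analysis together reproducibly.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
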