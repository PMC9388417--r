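Package: anticipatr
Title: Active-Inference Simulations of Anticipation in Striking Sports
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Discrete-state active-inference (POMDP) agents for studying
    skilled anticipation in striking sports such as cricket and baseball.
    Observers integrate prior contextual beliefs with early sensory cues by
    precision weighting, select anticipatory actions by minimising expected
    free energy (risk plus ambiguity, optionally novelty), and learn across
    trials through Dirichlet concentration-parameter updates. Includes
    generative-model builders for a simple and a reward/information trade-off
    scenario, an exact belief-updating engine, seeded trial-sequence
    environments with congruency and volatility manipulations, batch
    experiment runners with tidy outputs, and a small command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    rlang
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
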