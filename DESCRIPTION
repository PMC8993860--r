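Package: condval
Title: Simulation and Analysis of Conditioned Value Learning and Its Behavioral Use
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Generative simulation and analysis tools for probabilistic
    Pavlovian conditioning paradigms in which neutral cues acquire value
    through pairing with appetitive or aversive reinforcers, and for a
    subsequent instrumental approach-avoid task probing the use of that
    learned value. Provides counterbalanced trial-schedule construction;
    Rescorla-Wagner agents that emit reaction times, visual-analogue-scale
    ratings, approach/avoid choices, four-alternative recall responses and
    cardiac inter-beat-interval series; grid-search estimation of learning
    rates from reaction-time series; residualized-change learning scores and
    expected-use scores with per-reinforcer k-means phenotype clustering;
    sign-flip permutation tests; and inter-beat-interval resampling with
    epoch extraction. Synthetic cohorts with planted learn-by-use phenotype
    mixtures make every pipeline stage verifiable by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    cluster,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
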