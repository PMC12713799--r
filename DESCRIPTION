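Package: dreamcue
Title: Timer-Based Targeted Dream Incubation Sessions and Thought-Report Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for running sensor-free, timer-driven targeted dream
    incubation (TDI) sessions for hypnagogia and freely moving thought
    (FMT), and for analysing the resulting data: vigilance-based cohort
    screening, thought-report sentence preparation, cue-incorporation
    tallies with inter-rater agreement and rate statistics, sentence
    embedding derived prompt-centrality and temporal-coherence measures
    with random-intercept mixed models, a 13-item thought-probe battery
    with Benjamini-Hochberg corrected contrasts, precision-matrix partial
    correlations, common-factors parallel analysis and maximum-likelihood
    exploratory factor analysis with oblimin rotation, plus a synthetic
    cohort generator with known ground truth for offline validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    lme4,
    nnet
Suggests:
    testthat (>= 3.0.0),
    withr,
    e1071,
    jsonlite,
    optparse
Config/testthat/edition: 3
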