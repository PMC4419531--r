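Package: blinkstat
Title: Attentional-Blink Curve Models, Suppression-Ratio Artifact
    Simulation and Temporal-Order Error Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing dual-target rapid serial visual
    presentation (RSVP) experiments on the attentional blink (AB).
    Provides a generative inverted-gamma model of accuracy-by-lag curves,
    Monte-Carlo simulation showing how suppression-ratio baseline
    normalisation manufactures spurious group-by-lag interactions under a
    pure baseline-shift null, a trial-level synthetic RSVP data generator,
    two-way mixed ANOVA with simple effects and Bayes factors for the
    interaction term, logistic- versus exponential-decay model comparison
    for temporal order (swap) errors, and pooled-variance t tests
    recomputed from published summary statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    minpack.lm,
    lme4,
    pracma,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
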