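Package: cardiometa
Title: Own-Heart-Sound Recognition Analysis: Binomial Chance Classification,
    Type-2 Signal Detection (meta-d') and Interoceptive Accuracy
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Statistical pipeline for forced-choice own-heart-sound
    recognition experiments. Classifies subjects as SELF, NON-DISCRIMINATOR
    or OTHER with an exact binomial chance model; tests group distributions
    with chi-square goodness-of-fit and Cohen's omega; computes the Schandry
    heartbeat-counting interoceptive accuracy index; estimates type-1
    sensitivity (d') and metacognitive sensitivity (meta-d') by sum-square-
    error fitting of type-2 confidence-rating data; and runs the cohort
    inference layer (paired contrasts, correlations, Williams-Steiger test
    for dependent correlations, Kruskal-Wallis). Includes a seeded Gaussian
    signal-detection observer simulator with tunable metacognitive noise so
    every stage is testable without raw data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
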