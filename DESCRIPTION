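Package: tbwindow
Title: Temporal Binding Window Estimation from Audiovisual Simultaneity Judgments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the audiovisual simultaneity-judgment (SJ) paradigm:
    construction of SOA-balanced experimental designs with apparatus delay
    arithmetic, simulation of synthetic observers from a two-sided logistic
    psychometric model with lapses and trial rejection, estimation of each
    participant's temporal binding window (TBW) by side-split binomial
    regression with a 50-percent simultaneity criterion (with Jeffreys-penalized
    fits under separation), and the group-level inferential layer used in SJ
    studies: paired t-tests with Cohen's d (dz), fully within-subject 2x2
    ANOVA with partial eta squared, and exact noncentral-t power analysis for
    paired designs. A pipeline function and a thin command-line script tie the
    stages together reproducibly.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0),
    ggplot2,
    jsonlite,
    optparse
Config/testthat/edition: 3
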