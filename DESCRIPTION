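Package: carerbws
Title: Best-Worst Scaling Valuation Pipeline for the ASCOT-Carer Instrument
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reusable pipeline for profile-case (case 2) best-worst scaling
    valuation of the ASCOT-Carer instrument (7 quality-of-life domains with
    4 outcome levels each). Constructs a 32-scenario orthogonal main-effects
    plan blocked into 4 blocks of 8 choice tasks, simulates sequential
    best/worst/second-best/second-worst choices under a scale-adjusted
    multinomial logit (S-MNL) data-generating process with positioning
    effects and respondent-group scale heterogeneity, fits the exploded
    sequential S-MNL likelihood by maximum likelihood with cluster-robust
    sandwich covariance, and post-processes fitted coefficients into
    population-reweighted preference weights rescaled so that possible total
    scores span exactly 0 to 1, together with a scorer for carer
    quality-of-life states.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    Matrix,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
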