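Package: statehmm
Title: Behavioral Performance-State Segmentation with Multinomial GLM-HMMs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Segments rodent two-alternative choice behavior into discrete
    performance states using hidden Markov models with multinomial
    generalized-linear-model emissions (three choice categories: left lick,
    right lick, no response). Provides exact forward-backward inference,
    expectation-maximization fitting under maximum-likelihood or
    maximum-a-posteriori objectives, cross-validated selection of the number
    of states, and cross-validated choice prediction. Companion analyses
    relate arousal and uninstructed movement (pupil diameter, face motion
    energy, locomotion speed) to the inferred states: pre-stimulus feature
    extraction with Savitzky-Golay conditioning, rolling trial-to-trial
    variability, per-subject optimal pupil diameter from cross-validated
    polynomial fits, quadratic state-probability regressions,
    state-conditioned pupil-movement correlations, transition-aligned
    variability, and permutation-calibrated RBF-SVM state decoding. A
    synthetic-experiment generator with known ground truth supports
    end-to-end validation of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    signal,
    e1071,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
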