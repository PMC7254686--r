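Package: trackgait
Title: Speed and Gait Inference from Bipedal Trackways
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts locomotor speed and gait of a bipedal trackmaker from
    trackway stride length. Implements Froude-number dynamic-similarity
    predictors (the Alexander walking model and the Thulborn-Wade fast-gait
    model, with the mean-of-two trotting rule and piecewise dispatch on
    relative stride length), species-specific gait-wise linear calibration
    with t-based prediction intervals and residual diagnostics, gait
    classification by relative-stride thresholds or by overlap of calibrated
    stride ranges (with an ambiguity flag and the unclassifiable fraction),
    signed percent-error model evaluation against video ground truth, and a
    seeded generator of matched stride/speed datasets emulating field
    studies of birds moving over snow.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
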