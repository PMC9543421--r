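Package: corneatilt
Title: Corneal Tilt Estimation by Ray Tracing and Mediation Analysis of
    Scheimpflug Densitometry
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Estimates corneal tilt (angle alpha, the three-dimensional
    angle between the visual and optical axes of the eye) from exported
    anterior and posterior corneal elevation maps by vector Snell ray
    tracing and Levenberg-Marquardt rotation optimisation. Provides the
    Scheimpflug regional densitometry geometry (concentric zones and
    depth layers on the standardised greyscale-unit scale), a synthetic
    generator for tilted biconic corneas and for cohorts calibrated to
    printed age/tilt/densitometry statistics, and simple mediation
    analysis (paths a, b, c, c-prime, percentile-bootstrap indirect
    effect) to study age as a confounder of the tilt-densitometry
    correlation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    minpack.lm,
    stats,
    tools,
    utils,
    yaml
Suggests:
    ggplot2,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
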