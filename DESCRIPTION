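Package: flatrode
Title: Differential Flatness Control Synthesis Under Smooth Random Fluctuations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for certifying flat outputs of control-affine generative
    models, deriving functional parametrisations and linearising feedback,
    and synthesising flatness-based tracking controllers that operate
    pathwise under periodic smooth random fluctuations (band-limited
    Gaussian trigonometric sums). Includes the smooth-random-function
    sampler with exact calculus and tube-exceedance bounds, polynomial
    point-to-point steering, delay predictors (delayed observer and
    integral predictor) for delta-flat systems, generalised-coordinate
    (linearised differentiation) operators, and worked oculomotor and
    Bergman glucose-insulin demonstrations with active-inference
    discrepancy and risk metrics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    jsonlite,
    pracma,
    ggplot2,
    generics
Suggests:
    testthat (>= 3.0.0),
    withr,
    Matrix,
    optparse,
    deSolve,
    knitr
Config/testthat/edition: 3
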