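Package: rhythmprior
Title: Scalar-Timing Mixture Priors for Rhythm Interval Categories
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for modelling why durations in musical rhythms gravitate
    toward small integer ratios. Implements a Gaussian-mixture prior over
    inter-onset-interval (IOI) categories whose standard deviations obey the
    scalar property of timing (Weber's law, sigma = s * mu), closed-form
    algebra linking category overlaps to the ratios between adjacent category
    means, iterated-reproduction (transmission chain) simulation with scalar
    perceptual and motor noise, parameter-space exploration, and a
    tied-variance expectation-maximization fitter for estimating the Weber
    fraction and category means from IOI data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
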