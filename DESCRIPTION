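Package: mcmuniquac
Title: Matrix-Completion UNIQUAC for Predicting Activity Coefficients and
    Vapor-Liquid Equilibria
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Hybrid thermodynamic modeling of liquid mixtures that embeds a
    low-rank matrix-completion model of symmetric pair-interaction energies
    into the UNIQUAC Gibbs-excess-energy model. Latent feature vectors per
    component reconstruct the full symmetric matrix of unlike interaction
    energies from sparse binary-mixture activity-coefficient data, so that
    activity coefficients -- and from them isobaric vapor-liquid equilibria,
    azeotropes and multicomponent bubble points via the extended Raoult's
    law -- can be predicted for component pairs never studied experimentally.
    Includes maximum-a-posteriori and mean-field variational inference with
    analytic gradients, conventional per-system UNIQUAC baselines in both the
    symmetric-U and asymmetric-deltaU parameterizations, a consistency test
    for independently fitted deltaU parameters, a synthetic-data generator
    emulating sparse experimental databases, and a command-line pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
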