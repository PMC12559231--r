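Package: reslimit
Title: Modelling the Resolution Limit of Human Vision Across the Visual Field
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for measuring and modelling the highest display resolution
    the human eye can resolve, in pixels per visual degree (ppd), for
    achromatic and chromatic (red-green, yellow-violet) patterns at the fovea
    and in the periphery. Provides visual-acuity and display-geometry unit
    conversions (Snellen, minimum angle of resolution, ppd, cpd, display
    lines, ppi); a log-linear contrast-sensitivity model of the resolution
    limit as a function of retinal eccentricity with least-squares fitting; a
    Gaussian population model with percentile queries and ideal-display
    calculators; a simulated QUEST adaptive two-interval forced-choice
    psychophysics engine with maximum-likelihood psychometric fitting and
    modified Z-score outlier rejection; synthetic observer populations and
    grating stimulus generators; and an eccentricity-dependent foveated image
    filter built on a DKL opponent-colour decomposition and a Laplacian
    pyramid.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    png
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
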