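Package: speckletex
Title: Speckle Texture Analysis of OCT Volumes for Label-Free Detection of
    Neuronal Degeneration
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Texture-based analysis of optical coherence tomography (OCT)
    image stacks for the label-free detection of early neuronal degeneration.
    Provides a synthetic speckle phantom generator with a controllable
    degeneration parameter, stack preprocessing (reflection clipping,
    FFT notch filtering of fixed-pattern line artifacts, coverslip detection
    and tilt removal), automatic and seeded region-of-interest masking with
    in-ROI histogram equalization, a 65-feature speckle texture
    parameterization (local statistics, intensity moments, gray-level
    co-occurrence statistics, binary granulometry, directional complex
    wavelets), Gaussian-mixture class models selected by AIC with
    Mahalanobis-distance classification and leave-one-subset-out
    cross-validation, sequential forward feature selection scored by a
    Bernoulli-error BIC, and Sammon projection with a Texture Index that
    tracks progressive texture change along the maximum-variance axis.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    tiff,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    MASS,
    mclust
Config/testthat/edition: 3
RoxygenNote: 7.3.3
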