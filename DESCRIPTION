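Package: walksum
Title: Frequency-Dependent Communication Architecture of Structural
    Connectomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Derives the frequency-dependent communication architecture of a
    weighted structural connectome from its walk-sum transfer function (the
    matrix resolvent with delay phase), decomposed into an in-phase
    integrative channel and a quadrature routing channel.  Provides bare and
    dressed (damped-harmonic local gain) resolvents, distance-binned channel
    profiles and rank correlations, the Q-crossover and channel-divergence
    statistics, a prediction battery, Laplacian eigenmode projections,
    Welch cross-spectral coherency estimation for empirical comparison, a
    noise-driven Wilson-Cowan negative control, grid-search dressing fits
    with leave-one-dataset-out cross-validation, and synthetic
    distance-embedded connectome and time-series generators for testing.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
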