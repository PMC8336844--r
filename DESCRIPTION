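Package: ptfcolony
Title: Stochastic Models of OCT4 Regulation in Growing Pluripotent Stem-Cell Colonies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis of intra-cellular pluripotency
    transcription-factor (OCT4) dynamics in a growing human pluripotent
    stem-cell colony. Provides exact circulant-embedding (Davies-Harte)
    generation of fractional Gaussian noise, Hurst-exponent estimation by
    detrended fluctuation analysis and rescaled range, an agent-based colony
    model with probabilistic cell cycles and division-time inheritance, a
    family of stochastic-logistic dynamics for OCT4 (additive noise,
    multiplicative noise, a noise switch, time-dependent carrying capacity,
    and Allee-effect differentiation), and the summary statistics used to
    characterise anti-persistent fluctuations, distribution skew, mode
    shifts and fate separation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
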