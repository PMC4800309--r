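Package: hmpr
Title: Affective State Estimation from Skin Conductance by Higher-Order
    Multivariable Polynomial Regression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates continuous affective valence and arousal from
    event-related skin conductance. Decomposes averaged skin-conductance
    segments into a tonic level, the decaying tail of a previous response,
    and a four-parameter pure skin conductance response (SCR) waveform by
    Levenberg-Marquardt nonlinear least squares; statistically extends
    small per-stimulus feature tables into n(n-1)/2 mean- and
    variance-preserving pseudo-observations; fits higher-order
    multivariable polynomial models by truncated-SVD least squares with
    backward elimination of insignificant terms; selects the polynomial
    order by an Index score (Pearson correlation divided by mean squared
    error); and analyses fitted valence and arousal surfaces through
    their gradient fields. Includes a synthetic-data generator emulating
    a three-class (pleasant, neutral, unpleasant) picture-viewing
    experiment, CSV and trace file input/output, and an end-to-end
    pipeline with a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    minpack.lm,
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite,
    yaml
Suggests:
    optparse,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
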