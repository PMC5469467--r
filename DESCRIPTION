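Package: breathseg
Title: Automated Breath Detection in Airflow and Epiglottic Pressure Signals
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Automated detection of inspiratory and expiratory onsets in
    respiratory airflow or epiglottic pressure recordings, robust to baseline
    drift and variable mask pressures. Inspiratory onsets are located as
    extrema of the second derivative of a cubic smoothing spline fitted to
    the rising (flow) or falling (pressure) limb of each breath; expiratory
    onsets come from the per-breath drift-corrected integrated volume (flow)
    or a line-waveform intersection (pressure). Includes a synthetic
    flow-signal generator (gated sinusoid with amplitude modulation, white
    noise and a fractional-Gaussian-noise baseline trend via the Davies-Harte
    algorithm), per-breath respiratory parameters (Ti, Te, Ttot, PIF, Vt,
    minute ventilation, nadir pressure), and validation statistics (onset
    matching, error summaries, Bland-Altman, linear regression).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
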