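Package: wavesel
Title: Robust Wavelength Selection and Input Scaling for PLSR Calibration
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Wavelength selection for near-infrared (NIR) multivariate
    calibration by input scaling rather than hard deletion. Implements
    NIPALS partial least squares regression (PLSR), the orthogonal
    projections to latent structures (OPLS) decomposition with predictive,
    orthogonal and total variable-importance-in-projection (VIP) scores,
    Monte Carlo uninformative variable elimination (MCUVE) reliability
    coefficients, and a robust cut-off based on a one-sided normal
    tolerance interval on the median and MAD of artificial-noise
    reliabilities. The three-step mod-VIP-MCUVE pipeline rescales the
    predictor matrix first by OPLS-VIP total scores and then by MCUVE
    reliabilities before the final PLSR fit. A seeded synthetic-data
    generator and a scenario-by-method Monte Carlo benchmark reproduce the
    method's simulation study; cross-validated component selection and the
    RMSE, R2, RPD and SE evaluation statistics are included.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
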