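Package: phasecf
Title: Coupling Functions Between Cardiovascular and Cerebrospinal Oscillations
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Analysis of directed phase coupling between blood-pressure (BP)
    and subarachnoid-space-width (SAS) oscillations during paced slow
    breathing. Provides a synthetic generator for the four-stage slow-breathing
    protocol with known ground truth, signal conditioning and phase extraction
    (moving-average detrend, z-normalisation, zero-phase Butterworth bandpass,
    analytic-signal protophase and protophase-to-phase transformation), Morlet
    continuous wavelet analysis, windowed dynamical Bayesian inference of
    coupled phase-oscillator models, coupling-function reconstruction on the
    torus with directionality, strength and polar-similarity measures, cycle
    phase permutation surrogates, and Friedman/post-hoc stage statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
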