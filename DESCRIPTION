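Package: mmbreath
Title: Multimodal Breath Analysis from Wearable Impedance Pneumography
    and Lung Sounds
Version: 0.1.0
Authors@R:
    person("Analysis", "Pipeline", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Signal conditioning, breath and breathing-phase detection,
    signal-quality assessment, and phase-contextualized spectral feature
    extraction for simultaneous transthoracic bioimpedance (impedance
    pneumography) and chest-wall lung-sound recordings. Provides per-breath
    respiratory timing features (respiratory rate, inspiration and
    expiration times and their ratios), subband spectral integrated
    intensities of breath sounds computed separately for inspiration and
    expiration, robust median-absolute-deviation outlier cascades, windowed
    feature time series, and cohort-level nonparametric statistics with
    principal component analysis. Includes a synthetic-recording generator
    with ground-truth breath annotations so the full pipeline can be
    exercised and validated without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
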