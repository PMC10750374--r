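Package: mstateri
Title: EEG Microstate and Band-Power Analysis for Residual-Inhibition Studies
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Simulation and analysis of multichannel resting-state EEG for
    two-group, three-condition residual-inhibition study designs. Provides a
    synthetic-EEG generator with known microstate structure, deterministic
    preprocessing (resampling, zero-phase FIR band-pass and notch filtering,
    average referencing, fixed-length epoching with amplitude-based rejection),
    Welch power spectral density estimation with a nine-band decomposition,
    a full EEG microstate pipeline (global field power, GFP-peak extraction,
    polarity-invariant atomize-and-agglomerate hierarchical clustering and
    modified k-means, cross-validation and Krzanowski-Lai model selection,
    two-level template derivation, back-fitting, temporal metrics, and
    transition syntax), and a statistical layer (t-tests, chi-squared,
    mixed-design ANOVA, simple effects, Benjamini-Hochberg FDR, and
    metric-score correlation), orchestrated by a config-driven pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    data.table,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
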