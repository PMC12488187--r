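Package: patchpace
Title: Zone, Speed, and Deceleration Tuning of Striatal Calcium Activity in the Light/Dark Box
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Analysis pipeline linking striatal patch (striosome) neuron calcium
    activity to behavior in a light/dark-box assay. Segments tracked trajectories
    into light/dark zones, zone transitions with body-in-light (BIL) and
    body-in-dark (BID) windows, and acceleration events; conditions miniscope
    delta-F/F and fiber-photometry signals (noise-floor thresholding,
    max-normalization, double-exponential detrending) and detects fluorescence
    events; classifies per-neuron tuning to zone (rank test with Bonferroni
    control), speed (Spearman then quadratic fallback), acceleration versus
    deceleration (rank-based auROC preference index and
    deceleration-prediction flag), and transition activity/selectivity;
    quantifies signal-behavior coupling by event-windowed lagged
    cross-correlation; and estimates the BIL effect on speed or fluorescence
    with a bootstrap confidence interval. Includes a seeded synthetic-session
    generator (trajectory plus calcium traces with ground-truth labels) so
    every stage is verifiable without raw recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    zoo,
    jsonlite,
    yaml,
    minpack.lm
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
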