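Package: fogsense
Title: Freezing-of-Gait Detection and Phenotyping from Wearable Gyroscope and Surface EMG Signals
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis stack for bilateral shank-worn sensors recording z-axis
    angular velocity and surface electromyography (sEMG) of the tibialis
    anterior and gastrocnemius in Parkinson's disease gait studies. Implements
    threshold-based step-window segmentation of the smoothed gyroscope trace,
    a per-step freezing-of-gait (FOG) index R (peak normalized angular
    velocity over the simultaneous sEMG envelope), stance-phase rejection,
    episode aggregation and step-level evaluation against interval
    annotations; a frequency-domain phenotype index PI (max over geometric
    mean of the band-limited power spectral density of the fused bilateral
    sEMG-by-gyro product) separating shuffling-forward from
    trembling-in-place FOG; antagonist-muscle activity type (contraction vs
    stretching, from the sign of the low-frequency sEMG component) and
    intensity decoding with step-aligned ensemble averaging; and a seeded
    synthetic gait generator producing bilateral recordings with ground-truth
    annotations for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    signal,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
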