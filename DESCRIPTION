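Package: ehgkit
Title: Slow-Wave Envelope Enhancement and Contraction Detection for
    Multi-Channel Electrohysterography
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for enhancing abdominal-surface electrohysterography (EHG)
    recordings by multiplying the contraction-band fast wave (0.34-1 Hz) with
    the sliding-window RMS envelope of the slow wave (0.01-0.1 Hz), and for
    evaluating the enhancement: zero-phase Butterworth band-splitting and
    polyphase resampling, channel-quality screening, windowed-energy quality
    metrics (skewness, kurtosis, peak-to-average-energy ratio) with
    spike-artifact quantile trimming, energy-threshold contraction detection
    with ROC/AUC scoring against tocodynamometer-derived binary masks,
    convex-hull signaling-distance analysis over electrode arrays, paired
    nonparametric comparisons, and a seeded multi-channel EHG simulator with
    contraction ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    tools,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    signal,
    optparse
Config/testthat/edition: 3
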