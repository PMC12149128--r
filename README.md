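# ehgkit

Slow-wave envelope enhancement and contraction detection for multi-channel
electrohysterography (EHG).

## What problem this solves

EHG monitors uterine contractions non-invasively through abdominal surface
electrodes. Contraction monitoring conventionally uses the **fast wave**
(0.34–1 Hz), but that band is weak and easily swamped by motion artifact
and electrical noise in a labor ward, so energy-threshold contraction
detectors fail on many channels of a multi-electrode array. The **slow
wave** (0.01–0.1 Hz) recorded by the same electrodes is several times
larger, far more noise-robust, and its amplitude tracks contractions.

`ehgkit` enhances the fast wave by reweighting it with the slow wave's
local amplitude:

```
en(t_i) = RMS_slow(t_i) · f(t_i)
```

where `RMS_slow` is the sliding-window (10 s) root-mean-square envelope of
the slow wave and `f` the fast wave, both at a 5 Hz working rate. The
envelope is large during contractions and small between them, so the
product suppresses baseline noise and sharpens the contraction/baseline
contrast that threshold detectors rely on.

The package implements the full evaluation stack around that operation:

* **I/O** — EDF and delimited recordings, electrode-layout CSVs,
  per-sample or interval contraction masks (TOCO-derived ground truth);
* **preprocessing** — zero-phase fourth-order Butterworth band-splitting
  in second-order sections, polyphase resampling to 5 Hz, fast-wave
  channel-quality screening (keep-interval [0.01, 0.3] mV);
* **quality metrics** — sliding-window energy; skewness, kurtosis and
  peak-to-average-energy ratio (PAER, dB) of the energy distribution after
  discarding energies above the 0.95 quantile (spike-artifact trimming);
* **detection** — energy thresholding over a 121-point z-score grid
  (μ ± 3σ, step 0.05σ), per-sample ROC against a reference mask, trapezoid
  AUC, Youden-optimal threshold, and an exact rank-AUC reference;
* **spatial analysis** — high-consistency channel sets (AUC ≥ 0.8),
  channel and distance growth ratios, and convex-hull signaling distance
  (mean distance of hull vertices to their centroid in the y-projected
  frontal plane);
* **statistics** — paired two-sided Wilcoxon signed-rank comparisons
  (exact for ≤ 25 non-zero pairs), median/IQR summaries;
* **simulation** — a seeded multi-channel EHG generator with co-occurring
  slow/fast contraction bursts, distance-dependent attenuation from a
  contraction origin, white noise, spike artifacts, and exact ground-truth
  masks, so everything is testable without clinical recordings.

## Worked example

Simulate a low-SNR recording, run the pipeline, and compare fast-wave
against enhanced detection:

```r
library(ehgkit)

sim <- make_suite("low_snr", seed = 7, n_channels = 20, n_recordings = 1)[[1]]
sim$recording
#> <ehg_recording> 20 channel(s) x 153600 samples @ 256 Hz [raw], 600.0 s

pre  <- preprocess_recording(sim$recording)   # band-split, 5 Hz, screen
#> channel quality: 20/20 kept
fast <- apply_screen(pre$fast, pre$quality)
slow <- apply_screen(pre$slow, pre$quality)
enh  <- enhance_recording(fast, slow)
#> <ehg_recording> 20 channel(s) x 3000 samples @ 5 Hz [enhanced], 600.0 s

mask <- truth_mask(sim$truth, 5, n_samples(fast) / 5)
auc_fast <- channel_auc_map(fast, mask, sim$layout)
auc_enh  <- channel_auc_map(enh,  mask, sim$layout)
median(auc_fast$auc); median(auc_enh$auc)
#> 0.661
#> 0.829

compare_bands(recording_metrics(fast), recording_metrics(enh))
#>     metric  n  p_value fast_median enhanced_median
#> 1 skewness 20 1.91e-06       0.314            2.67
#> 2 kurtosis 20 1.91e-06       2.576           11.22
#> 3     paer 20 1.91e-06       5.432           20.23

sp <- spatial_comparison(auc_fast, auc_enh, sim$layout)
sp$fast$set$count; sp$enhanced$set$count; round(sp$enhanced$d, 1)
#> 0
#> 11
#> 155
```

Reading the numbers: on channels where the fast wave is near the noise
floor, envelope weighting lifts the median detection AUC from 0.66 to
0.83, raises all three contrast metrics (each paired signed-rank p ≈
2e-6 over 20 channels), and grows the high-consistency set from 0
channels to 11 spanning a 155 mm signaling distance — no fast-wave
channel reaches the AUC ≥ 0.8 consistency bar on this recording, so its
signaling distance is undefined (`NA`).

A command-line front end wrapping the same functions is installed at
`exec/ehgkit` (subcommands `simulate`, `preprocess`, `enhance`,
`metrics`, `detect`, `spatial`, `stats`, and `run` for a YAML-configured
end-to-end pass; see `default_pipeline_config()`).

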