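---
title: "Slow-wave envelope enhancement of uterine EHG: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Slow-wave envelope enhancement of uterine EHG: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ehgkit)
```

## The problem

Electrohysterography (EHG) records uterine electrical activity from surface
electrodes on the abdomen. The conventional contraction-monitoring band is
the *fast wave*, 0.34–1 Hz. It is small (tens of microvolts to a few tenths
of a millivolt), and in a labor-and-delivery room it is badly contaminated
by motion artifact, electrode noise and crosstalk, so energy-threshold
contraction detectors produce false alarms and misses on many channels of a
multi-electrode array.

The same electrodes also carry a *slow wave*, 0.01–0.1 Hz. It is several
times larger than the fast wave and much more robust to these noise
sources, and its amplitude rises during contractions. `ehgkit` implements
an enhancement that exploits this: the fast wave is reweighted pointwise by
the local amplitude of the slow wave.

## The enhancement

With $s(t_i)$ the slow wave and $f(t_i)$ the fast wave (both at the 5 Hz
working rate), the enhanced signal is

$$\mathrm{en}(t_i) = \mathrm{RMS}_{\mathrm{slow}}(t_i)\, \cdot f(t_i),$$

where $\mathrm{RMS}_{\mathrm{slow}}(t_i)$ is the root-mean-square of
$s$ over a sliding window centered on $t_i$. Because the envelope is large
inside contractions and small between them, the product suppresses
baseline fast-wave noise while leaving contraction bursts in place — the
contrast that a threshold detector needs. The output is in mV²; nothing
downstream depends on its absolute scale (the quality metrics are scale
invariant and detection thresholds are swept relative to the energy
distribution), so no re-normalization is applied.

### Window semantics

The envelope window is $n = 50$ samples — 10 s at 5 Hz — with inclusive
centered bounds $[i - \lfloor n/2 \rfloor,\, i + \lfloor n/2 \rfloor]$,
clipped at the series ends. Two consequences are worth stating plainly:

* a full interior window holds $n + 1 = 51$ samples, and
* the divisor is always the *actual* number of samples in the clipped
  window, so the envelope is unbiased at the edges (the RMS of a constant
  series is that constant at every index, first and last included).

The same windows, without the divisor, define the sliding **window
energy** $e_i = \sum_j f(t_j)^2$ used everywhere downstream. The 10 s
width is physiological: contractions last 30–90 s, so windows above ~30 s
oversmooth them away (the pipeline warns at that point), while much
shorter windows chase local structure such as spike artifacts.

## Preprocessing

Band-splitting uses fourth-order Butterworth band-passes (0.01–0.1 Hz and
0.34–1 Hz), applied forward and backward. Zero-phase filtering is a
deliberate choice the recording chain forces: detection is scored per
sample against a tocodynamometer (TOCO) mask, so the filters must not
shift contraction timing. Forward–backward application doubles the
effective attenuation order; the amplitude checks in the tests account for
this.

Numerically, the filters are designed in zero–pole–gain form and run as
cascaded second-order sections. At the native 2048 Hz rate the normalized
lower cutoff is $10^{-5}$ of Nyquist; expanding the transfer function into
eighth-order polynomial coefficients collapses them to ~1e-15 and is
unusable, while biquad sections remain well conditioned. Start-up
transients are absorbed by odd-symmetric edge extension whose length is
three time constants of the band's lower edge; the first/last 30 s are
additionally flagged in recording metadata rather than trimmed, since no
published trimming rule exists.

Both bands are then decimated to 5 Hz by rational polyphase resampling
(factor 5/2048 in lowest terms — a windowed-sinc kernel evaluated only at
the output instants, never materializing the upsampled series). Each
polyphase branch is normalized to unit DC gain, so constants survive to
machine precision and in-band tones to about $10^{-4}$. Both bands lie far
below the 2.5 Hz output Nyquist, so decimation loses no information.

Channel quality screening follows the fast wave: channels whose peak
fast-wave magnitude falls outside the closed interval [0.01, 0.3] mV are
excluded (too small: poor contact; too large: artifact). The peak is
measured at 5 Hz after discarding three filter time-constants at each end
so filter transients cannot decide a channel's fate; whether screening
preceded or followed decimation in the original recordings is not
documented, and applying it at 5 Hz is this package's choice.

## Quality metrics

The energy histogram of a channel separates into a baseline mode and a
contraction mode. Three statistics of the windowed-energy distribution
quantify that separation, computed over the whole channel without
segmentation:

* **skewness** $\frac{1}{N}\sum \left(\frac{e_i-\bar e}{\sigma}\right)^3$,
* **kurtosis** $\frac{1}{N}\sum \left(\frac{e_i-\bar e}{\sigma}\right)^4$
  (plain, not excess: a Gaussian scores 3), and
* **PAER** $= 10\log_{10}\left(\max(e)^2/\overline{e}^{\,2}\right)$ dB,
  the peak-to-average-energy ratio.

$N$ is the number of energy samples and $\sigma$ the population (divisor
$N$) standard deviation. All three are invariant under positive rescaling
of the input. Before computing them, energies above the empirical 0.95
quantile (linear-interpolation definition, `stats::quantile` type 7) are
*discarded*, not clipped: spike artifacts are short and huge, discarding
bounds their influence on all three metrics including PAER's maximum. The
trim is applied to the metric computation only, not to the detector —
the detector's threshold grid is defined on the full energy distribution.

## Contraction detection and ROC scoring

A contraction prediction at threshold $\theta$ is simply $e_i > \theta$
(strict; ties count as baseline). Thresholds sweep a z-score grid,
$\mu + k\cdot 0.05\,\sigma$ for $k = -60,\dots,60$ (121 values spanning
$\mu \pm 3\sigma$), with $\mu,\sigma$ the mean and sample standard
deviation of the untrimmed energies. Each threshold's mask is scored per
sample against the TOCO-derived reference mask — per-sample scoring is
chosen over event-level scoring because it needs no matching heuristics
and is deterministic. TPR/FPR pairs are anchored at (0,0) and (1,1) and
integrated by the trapezoid rule; the optimal threshold maximizes Youden's
$J = \mathrm{TPR} - \mathrm{FPR}$, ties resolving to the lower threshold
(higher sensitivity). The grid AUC approximates the threshold-free
rank (Mann–Whitney) AUC, which `rank_auc()` provides as a continuous
reference; on unimodal energy distributions the two agree to within the
grid resolution (~0.02), and the tests enforce that bound.

## Spatial consistency and signaling distance

Channels whose AUC against the TOCO mask reaches 0.8 (inclusive) form the
*high-consistency set*. Two summaries compare fast-wave and enhanced
sets: the channel growth ratio $r_c = (ch_E - ch_f)/ch_f$ and the distance
growth ratio $r_d = (d_E - d_f)/d_f$.

The signaling distance $d$ measures how far detectable contraction signal
spreads. Electrode positions are projected along the y axis (anterior →
posterior), collapsing depth onto the frontal x–z plane; the convex hull
of the projected set is taken, and $d$ is the mean Euclidean distance from
the hull vertices to their centroid, the centroid being the mean of the
hull *vertices* only (not of all set members, and not an area centroid).
The projected reading is the default because the published description of
the procedure is a projection, even though the distance formula is written
with three coordinates; `project_y = FALSE` keeps the 3-D coordinates of
the projected hull's vertices for the alternative reading. Degenerate sets
follow the same mean-distance formula: one point gives $d = 0$; two points
or a collinear set give the segment extremes as the hull and $d$ = half
the segment length. Collinear boundary electrodes are *excluded* from the
hull (strict vertices), which matters because they would enter the vertex
count $n$; the brute-force extreme-point oracle in the tests pins this
convention.

## Statistics

Per-channel fast/enhanced metric pairs are compared with the two-sided
Wilcoxon signed-rank test, per subject or pooled. Zero differences are
dropped (the standard treatment; the alternative zero-handling was not
documented in the source procedure), tied absolute differences get
averaged ranks, and the null is enumerated exactly up to 25 non-zero
pairs (no ties), falling back to the normal approximation with continuity
correction. Summaries are median and IQR throughout, as the paired
differences are not normal. One honest limitation of subject-*count*
comparisons: with only 5 subjects the two-sided exact test cannot go
below $p = 0.0625$, so a claim of $p < 0.05$ at $n = 5$ is not reproducible
under this test; the package reports the exact p-value it computes. No
multiple-testing correction is applied.

## The synthetic generator

Real labor EHG with aligned TOCO annotations is not publicly available,
so every stage is exercised against a seeded simulator
(`sim_config()`, `simulate_recording()`, `make_suite()`). It emulates the
features the method depends on:

* contractions of 30–90 s with inter-onset gaps of 120–300 s (several per
  20-minute recording), known exactly to the ground-truth mask;
* co-occurring slow-wave and fast-wave bursts, realized as white noise
  filtered through the *same* Butterworth designs the preprocessing uses
  (spectral consistency by construction), with raised-cosine on/off ramps
  of 5 s and `slow_amp > fast_amp` enforced;
* exponential amplitude decay $e^{-\mathrm{dist}/\lambda}$ from a
  contraction origin on a half-cylindrical "abdomen" electrode layout —
  this is what gives the spatial analysis its direction of effect;
* white Gaussian measurement noise everywhere, and optional spike
  artifacts (0.2 s, 10× the fast-wave amplitude) to exercise quantile
  trimming.

It does **not** model myometrial electrophysiology (no action-potential
propagation, no conduction velocity, no deformation of the abdominal
surface), channel-specific noise spectra, electrode drift, or the
imperfect alignment between mechanical (TOCO) and electrical activity.
Passing tests therefore demonstrate that the pipeline behaves correctly
on signals with the stated spectral, timing and spatial structure — not
that clinical performance figures transfer.

Defaults in `sim_config()` are the recording conditions of interest
(2048 Hz native rate, ~20 min). The named suites in `make_suite()` are
test fixtures and deliberately run at a 256 Hz native rate and 600 s so
that full-pipeline property checks over dozens of seeded runs complete in
minutes; both analysis bands sit far below Nyquist at either rate, so the
band-limited content the pipeline sees is unchanged. The `low_snr` preset
was calibrated once so that fast-wave channel AUCs land around 0.6–0.8 —
the regime where enhancement has headroom — and then pinned; `high_snr`
makes contractions obvious in the fast wave (AUC > 0.9), where
enhancement is expected to change little. On mid-SNR channels the
envelope's 5 s on/off ramps can even cost the enhanced signal a little
rank-AUC at contraction edges; the suites' regimes bracket this.

## Numerical conventions worth knowing

* Sample indexing is 0-based in all documentation of timing; time of
  sample $i$ is $i/f_s$. Interval masks are half-open $[start, end)$,
  rasterized by flooring the start and ceiling the end, conservatively
  including contraction edges.
* Delimited recordings are written with 17 significant digits and
  round-trip bit-identically; EDF quantizes to 16 bits.
* Quantiles everywhere (trimming, IQR) are linear-interpolation type 7.
* The threshold grid requires $\sigma > 0$; constant energy series are a
  hard error, as are single-class reference masks and all-zero paired
  differences.
* All simulator randomness flows from the single mandatory seed, and the
  global RNG state is restored afterwards.
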