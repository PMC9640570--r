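---
title: "Methods: ripple-coupled dendritic spike analysis on a synthetic forward model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ripple-coupled dendritic spike analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(swrdspike)
```

## Scope

`swrdspike` reimplements, as a tested analysis pipeline, the chain of
computations that links hippocampal sharp-wave ripples (SPW-Rs) in a local
field potential (LFP) to dendritic Ca^2+^ spikes (dSpikes) imaged along the
basal dendrites of parvalbumin-positive (PV+) interneurons:

1. ripple detection and featurization,
2. ΔF/F transient detection,
3. ripple–calcium coincidence and local-vs-global mode classification,
4. three-group event classification (low-ripple / high-ripple / doublet),
5. dendritic spatial threshold, hot spots, and propagation, and
6. supralinearity of summation during SPW-R doublets.

Because the original raw recordings are not publicly deposited, the package
ships a phenomenological forward model (`sim_config()`,
`simulate_session()`) that generates coupled LFP and dendritic fluorescence
with known ground truth. All tests, the numbered drivers under `analysis/`,
and the acceptance script run entirely on this synthetic substrate.

## The forward model

**LFP.** Each scheduled SPW-R sub-event is a Gaussian-windowed sinusoid at
the ripple carrier (180 Hz by default) superposed on a slow negative
sharp-wave deflection (Gaussian, 20 ms SD), embedded in 1/f ("pink")
background noise generated by spectral shaping. Four local hippocampal
channels carry the events with decreasing gains (so channel selection by
band power is well defined); a contralateral channel and a reference
channel carry noise only, except for optional bilateral artifacts used to
exercise the contralateral rejection rule. The background noise amplitude
(10 µV SD broadband) is a generator default chosen so that the 4 SD
envelope rule separates the two ripple amplitude classes from noise; it is
a documented modelling choice, not an empirical value.

**Event schedule.** Complexes arrive on a jittered grid at the configured
rate with a 500 ms refractory period, so that detection and merging tests
are unambiguous. Groups are drawn from the `(low, high, doublet)` mixture,
default `(0.4, 0.4, 0.2)`. Per-event ripple amplitudes are lognormal around
the class means (30 / 60 µV, log-SD 0.2) and per-event calcium scalings
lognormal around the class means (0.33 / 1.0, log-SD 0.3); at these
defaults the two singlet classes sit more than 3 SD apart in each log
feature, which is the separation regime the classification suite assumes.
Doublet inter-event delays are normal with mean 145.76 ms and SD 18.77 ms
(truncated to 60–250 ms); the second ripple of a doublet draws its
amplitude from the low class, while its calcium response is the first
response scaled by the doublet gain (2.92 by default). Sub-event durations
are normal around 35.6 ms. The first second of every session is kept
event-free so the early-baseline SD rule has clean data.

**Dendrites.** A dendritic spike's per-position peak amplitude is a
baseline ramp plus a logistic jump centered at the spatial threshold
(133.24 µm, steepness 8 µm) with Gaussian hot-spot bumps (FWHM 5.41 µm,
amplitude 0.5 ΔF/F) at distal centers; global (bAP-like) events decay
exponentially from the soma (length constant 150 µm) and occur between
SPW-R complexes. The temporal kernel is a difference of exponentials with
20 ms rise and 340 ms decay (the in vivo indicator decay), normalized to
unit peak. Activation propagates from the hot-spot center at 6.6 µm/ms out
to the invasion radius `speed × lead` (≈91 µm), beyond which the rest of
the segment activates synchronously at the full initiation lead (13.83
ms); this reconciles a finite mean lead with strictly linear lateral delay
near the center. Imaging noise is additive Gaussian in ΔF/F (SD 0.0461).
The calcium onset at the hot-spot center coincides with the ripple peak
(time zero); with the slow indicator kinetics the calcium peak then lags
the ripple peak by the kernel rise, which is why the package does not try
to reproduce a specific peak-to-peak jitter value.

**What the generator does not emulate.** Motion artifacts, neuropil
contamination, bleaching, indicator nonlinearity, biophysical (conductance)
dynamics, and 3D ribbon geometry are all outside the model. Passing tests
therefore demonstrate that the analysis recovers the parameters of this
phenomenological model under realistic noise, not that it would be robust
to every artifact of real two-photon data.

**Seeding.** A single master seed drives everything; each stage derives its
own stream (`derive_seed()`), so stages are independently reproducible and
reruns are bit-identical.

## Detection choices

**Ripples.** The band filter is the difference of two zero-phase Gaussian
low-pass kernels with cutoffs 150 and 500 Hz, `sigma = 1/(2π f_cut)`,
truncated at 4σ; the difference of two unit-sum kernels nulls DC exactly.
The power envelope is the squared filtered trace smoothed by a Gaussian of
SD `smooth_ms/2` (default 5 ms). The baseline for the 4 SD rule is the mean
and SD over event-free stretches found by a liberal first pass (median +
3 robust SD, dilated by 100 ms); moment statistics rather than MAD are used
for the spread because the squared-signal envelope is strongly skewed and a
MAD-based spread underestimates its tail. Supra-threshold crossings must
last at least 10 ms — band-limited noise produces brief 4 SD excursions a
few ms long, far below any physiological ripple, and the duration criterion
is what keeps the false-event rate negligible (< 1 per 10 s on pure noise).
On noise-free syntheses the baseline spread is zero and the threshold falls
back to 0.2 % of the peak envelope, segmenting events at the wavelet
support. Consecutive intervals merge into one complex when the total span
is strictly below 300 ms; three or more intervals become a `multi` complex
that is excluded from doublet statistics. Ripple cycles are counted as
positive-going zero crossings.

**Calcium.** ΔF/F uses a per-position 20th-percentile baseline (F0 has no single
standard definition; a percentile is robust to sparse transients). Detection operates on the spatially averaged trace of the
distal third of the segment (configurable), with the SD taken from the
first 100–500 ms. T3/T4 are the 2 SD crossings with sub-frame linear
interpolation; a candidate is accepted only when its 60 ms peak-window mean
itself exceeds the 2 SD criterion and the crossing persists for at least
two frames. Sub-threshold gaps shorter than 150 ms are treated as threshold
flutter on a decaying transient; within one interval, events are split at
troughs below half the smaller flanking peak provided the second peak rises
clearly above the trough (half the trough level or 6 baseline SDs,
whichever is larger). These two rules keep compound doublet responses whole
— their inter-event trough stays above ~75 % of the first peak at the
default kinetics — while separating ordinary events ≥500 ms apart.

**Modes.** A response is a local dSpike when amplitude rises with distance
(positive slope) and the distal (>150 µm) to proximal (<20 µm) mean ratio
exceeds 2; a global bAP when the profile is antagonistic (ratio < 1/2);
otherwise unclassified. The ratio criterion (R_min = 2) is this package's numeric
operationalization of the two antagonistic spatial profiles.

## Classification choices

The spectral-histogram split fits one- and two-component Gaussian mixtures
(`mclust`) and keeps two components only when BIC prefers them and the
means do not collapse within 0.1 pooled SD; the BIC step is needed because
a forced two-component fit of a unimodal sample still produces separated
means. The boundary is the valley of the fitted density between the means.
The low/high boundary is fit on singlet log areas — doublets form their own
mode and are already separated by the detector kind. The gap statistic
sorts log calcium areas and uses the mean distance to the six nearest
neighbours; the gap is sought strictly between the modes of a kernel
density estimate, because the neighbour distances in the distribution tails
are inflated and would otherwise masquerade as gaps in unimodal controls.
Significance is a two-sample t-test of the center four points against the
remaining interior points, reported in both the equal-variance and the
Welch variant. K-means runs in two steps (doublets by detector kind or
duration split, then K = 2 on standardized log Ca area × log peak-to-peak
of singlets) with 25 restarts under a fixed seed. The six-parameter product
score min–max normalizes duration, peak-to-peak, area, power, frequency and
Ca area to `(ε, 1]` and multiplies; the exact parameter set is configurable, since only the product
construction — not the identity of the six parameters — is prescribed. Natural logarithms are used throughout; histogram binning,
where needed, follows Freedman–Diaconis.

## Spatial estimation choices

The spatial threshold is the midpoint of a linear-baseline-plus-logistic
fit (`minpack.lm`); the jump must exceed 10 % of the profile range,
dominate the linear trend, and be genuinely sigmoidal (steepness below a
tenth of the position range) — otherwise the profile has no inflection and
the threshold is absent rather than zero. When the fit fails to converge, a
smoothed-spline second derivative maximum is used, accepted only above a
curvature floor. Hot spots are local maxima of the temporal-integral
profile with prominence ≥ 25 % of the dynamic range and separation ≥ 2
expected FWHM; FWHM is measured at half prominence with linear
interpolation. Onsets are 50 %-of-peak crossings (configurable 20–80 %)
with sub-frame interpolation. Propagation is summarized per side of the
hot spot with a two-segment fit — delay rising through the origin at `1/v`
up to a knee, then a plateau; the initiation lead is the median delay over
the outer 30 % of the side, and a side whose knee sits near the segment end
is censored (the spike was still propagating when the dendrite ended).

## Summation choices

"Amplitude" in all supralinearity ratios is the 60 ms peak-window mean,
consistent with transient detection; areas are reported alongside. The
delay used for the high+high and high+low mathematical sums is the
dataset's mean doublet delay, recomputed per run. Per-doublet gains are
estimated by scaling the high-ripple template to the doublet's first
response and measuring the residual second response; this is exact on
noise-free composed traces. With the generator's literal composition rule
(second kernel scaled by the 2.92 gain), the measured doublet also carries
the decaying tail of the first response, so the emergent high+high ratio is
about 47 %; the package reports this measured value rather than
calibrating the generator to any particular population figure. The temporal-dependence analysis bins per-doublet gains by delay,
reports the Spearman sign, and fits an exponential decay on log gains; the
default generator keeps the gain constant (`gain_decay_tau = Inf`), and a
finite decay constant can be configured for recovery studies.

## Problem sizes and runtime

The suite and the acceptance script use LFP at 10 kHz or 5 kHz (both far
above twice the 500 Hz cutoff and detection-equivalent to 20 kHz), sessions
of 6–420 s, 1–2 dendrites at 64 or 308 Hz imaging, 50-seed recovery
studies, and a 500-event feature-level study for classification — the
feature-level path (`simulate_event_features()`) shares the schedule's
amplitude structure without synthesizing hours of 20 kHz signal. These are
the package's chosen study sizes; the defaults of `sim_config()` remain the
full-rate values.

## Known limitations

- The two-step K-means and mixture split assume two singlet amplitude
  classes; graded continua will be split at an arbitrary boundary.
- The contralateral rejection rule assumes artifacts are band-limited
  enough to cross the contralateral 4 SD envelope threshold for ≥10 ms.
- Lead and speed estimation require the hot spot to sit well inside the
  imaged segment; hot spots near the segment end yield one-sided,
  censored estimates.
- The session container is a plain-text directory (CSV + JSON manifest),
  lossless to 15 significant digits; it is this package's own format,
  designed for transparent diffing and text-only pipelines.
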