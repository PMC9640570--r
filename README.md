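# swrdspike

Analysis pipeline linking hippocampal **sharp-wave ripples (SPW-Rs)** in the
local field potential to **dendritic Ca²⁺ spikes (dSpikes)** imaged along the
basal dendrites of parvalbumin-positive (PV+) interneurons in awake animals.

During SPW-Rs, a subset of PV+ dendrites fires regenerative, locally
initiated Ca²⁺ spikes whose amplitude jumps sigmoidally beyond a critical
somato-dendritic distance (the *spatial threshold*), initiates at confined
*hot spots*, and propagates both centripetally and centrifugally. When two
SPW-Rs arrive within a short window (a *doublet*, inter-event delay
~146 ms), dendritic summation is strongly supralinear: the arithmetic sum of
two singlet responses accounts for only about half of the measured compound
response. This package implements every analysis stage of that chain and a
synthetic forward model with known ground truth, so the whole pipeline is
testable without access to raw recordings.

## What it computes

- **Ripple detection** — band filtering as the difference of two zero-phase
  Gaussian low-pass filters (150/500 Hz), power envelope, 4 SD threshold
  over a robust event-free baseline, merging of supra-threshold intervals
  into complexes when the span `T22 − T1 < 300 ms` (singlet / doublet /
  multi), the five event features (duration, area ∫|x|dt, power ∫x²dt,
  zero-crossing frequency, peak-to-peak), time zero at the peak of |filtered
  LFP|, channel selection by band power and contralateral artifact
  rejection.
- **Ca²⁺ transients** — ΔF/F = (F − F₀)/F₀ with a percentile baseline,
  2 SD detection with the SD from the first 100–500 ms, T3/T4 crossings,
  60 ms peak-window amplitude, per-position amplitude profiles, 25 µm
  distance binning.
- **Coincidence & modes** — a response and a ripple are simultaneous when
  `[T3, Tpeak]` overlaps `[T1, T2]`; local dSpike vs global bAP calls from
  the antagonistic spatial profiles; total / per-dendrite / per-cell
  activation ratios.
- **Event groups** — low-ripple, high-ripple, doublet via two-Gaussian
  spectral-histogram decomposition, a six-nearest-neighbour gap statistic
  with a center-four t-test, two-step K-means, a six-parameter product
  score, and a consensus with an agreement report.
- **Dendritic geometry** — spatial threshold as the logistic inflection of
  the amplitude–distance profile, proximal linear fit, hot spots on the
  temporal-integral profile (FWHM at half prominence), onset maps at 50 %
  of peak with sub-frame interpolation, initiation lead and propagation
  speeds, branch-point correlation.
- **Doublet supralinearity** — ripple-aligned group averages, the
  high+high and high+low mathematical sums at the dataset's mean doublet
  delay, `ratio = 100 · peak(sum)/peak(measured)`, per-doublet gains by
  template subtraction, and their dependence on the inter-event delay.

## Worked example

The numbered drivers under `analysis/` run the full chain on a simulated
reference session (300 s, 10 kHz LFP, two dendrites):

```sh
Rscript analysis/01_simulate.R
Rscript analysis/02_detect_ripples.R
Rscript analysis/03_detect_transients.R
Rscript analysis/04_coincidence.R
Rscript analysis/05_classify_events.R
Rscript analysis/06_spatial_hotspots.R
Rscript analysis/07_doublet_summation.R
```

which prints, stage by stage:

```
Simulated 300 s at 10 kHz: 80 SPW-R complexes (15 doublets, 18.8%),
2 dendrites, 147 scheduled dendritic spikes, 10 global (bAP) events.

Detected 86 complexes (0 rejected on the contralateral channel).
Singlets: 71 (mean duration 32.1 ms); doublets: 15 (mean duration 177.5 ms,
mean inter-event delay 145.9 ms); doublet fraction 17.4%.

Detected 167 calcium responses across 2 dendrites.

Grouped 80 calcium-coupled events: doublet=15, high_ripple=31, low_ripple=34.
Gap statistic: p = 3.85e-12 (equal variance), 4.70e-02 (Welch).

Spatial threshold: 133.9 +/- 0.1 um (mean +/- SD over 2 dendrites).
151 hot spots: FWHM 5.70 +/- 0.74 um; propagation 6.6 um/ms.

Doublet summation (dendrite 1, 13 doublets vs 31 high singlets):
high+high mathematical sum = 48.5% of the measured doublet response;
mean per-doublet gain 2.86 at a mean inter-event delay of 147.3 ms.
```

Reading the output: the detector recovers the scheduled complexes and their
singlet/doublet kinds (the six extra complexes are doublets whose span drew
past 300 ms and therefore legitimately split); the estimated spatial
threshold (133.9 µm) and hot-spot FWHM (5.7 µm) recover the generator's
ground truth (133.24 µm, 5.41 µm); propagation is read off the onset maps
at the configured 6.6 µm/ms; and the high+high mathematical sum reaches
only ~48 % of the measured doublet response — the supralinearity that the
configured doublet gain (2.92, recovered as 2.86) produces. Each stage
writes its table under `results/`.

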