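---
title: "Tiling and aggregation for rPPG: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tiling and aggregation for rPPG: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tileppg)
```

## The problem

Remote photoplethysmography recovers the cardiac pulse from the tiny
periodic change in light reflected by facial skin, most visible in the
green channel because of haemoglobin absorbance. Averaging a fixed
midface region mixes strongly pulsatile skin with shadowed, occluded or
moving areas, which dilutes the pulse. Tiling and aggregation (T&A)
scores many small candidate regions and rebuilds the output signal from
the best of them. This vignette records how each stage is defined here,
which parameters matter, and which choices were genuinely open.

## Signal-quality metric (SNR-F)

Each tile's time series is linearly detrended and transformed with a
rectangular-window periodogram on the raw DFT grid. The normalisation is
Parseval-consistent: bin powers sum to the mean square of the detrended
signal, so band sums are variance contributions and their ratio is
scale-free. The score is

$$\mathrm{SNRF} = 10\log_{10}
  \frac{\sum_{|f-\mathrm{PR}|\le 0.15} P(f)}
       {\sum_{f \in [0.5,5]\setminus \mathrm{pulse}} P(f)}\ \mathrm{dB},$$

with the pulse interval clipped to the 0.5–5 Hz analysis band. Bin
membership is inclusive at both pulse-band edges; the residual set is the
remaining in-band bins, a deterministic partition. Degenerate ratios
(zero numerator or denominator, e.g. a noiseless tone or a constant
signal) saturate at ±60 dB with a `capped` flag, which keeps downstream
power-domain weights finite.

Numerical choices worth noting:

* **Detrend order 1 by default.** Sub-band baseline drift is the dominant
  nuisance below 0.5 Hz; a linear fit removes most of it without touching
  the analysis band. A linear detrend does perturb even bin-aligned tones
  at the ~1e-6 relative level (a sinusoid is not orthogonal to a ramp),
  so exact spectral identities hold under `detrend = 0` (mean removal
  only), which tests use where exactness is asserted.
* **Pulse-rate source.** The score needs a PR. Callers can pass the
  reference value; with `"auto"` a single recording-level PR is estimated
  as the in-band spectral peak of the unweighted all-tile mean and reused
  for *every* tile. Per-tile peak picking would let pure-noise tiles
  align the pulse band with their own largest fluctuation and corrupt the
  ranking.
* **Harmonics count as noise.** Pulse power at 2×PR and above falls in
  the residual band. Whether the original analysis counted harmonics as
  signal is unknown; counting them as noise is the stricter convention
  and is applied uniformly, so rankings are unaffected.
* **Tie-breaks.** The in-band argmax for PR estimation takes the lowest
  frequency on ties; best-n tile selection takes the lower tile id.

## Tiling

The midface ROI is a union of axis-aligned rectangles in 0-based,
half-open pixel coordinates. A 20×20 lattice is anchored at the ROI
bounding-box top-left; tiles fully inside the ROI are kept, partial edge
tiles dropped, and tiles are ordered row-major. The anchoring rule is a
choice — any fixed anchor reproduces "no gaps or overlap" — and the grid
is static for a recording because the synthetic faces do not move;
per-frame re-registration belongs to face tracking, which is out of
scope. The canonical fixture ROI (two 5×5-tile cheek blocks plus a
2×6-tile nose/lip strip) tiles into exactly 62 tiles, matching the scale
of a real midface at 720p; it reproduces the tile count, not anatomy.

## Aggregation

All five algorithms operate on the per-tile SNR-F scores at one global
PR:

* weights: dB scores can be negative, so the default mapping returns to
  the power domain, $w_k \propto 10^{s_k/10}$, which is non-negative and
  order-preserving; rank-based and min-shifted-linear mappings are
  available for sensitivity checks.
* best-n: n = 30 of 62 tiles by default, about half the midface.
* segmented modes: the recording is cut into 10 s segments (six for a
  60 s recording; a trailing fragment shorter than 2 s is merged), tiles
  are re-scored and re-selected per segment at the global PR (per-segment
  PR re-estimation is a flag), and segments are recombined.

Segment recombination was an open design point: the goal is to avoid
sharp discontinuities when the selected tile set switches. Tiles carry
different DC baselines, so each segment's aggregate is mean-centred
before recombination, neighbouring segment aggregates are blended with a
linear cross-fade over 2 s windows centred on each boundary (each
segment's selection defines a signal at *every* time point, so both
sides of a fade are well-defined), and the removed DC is restored as its
time average. A guard property checks that the largest boundary step
never exceeds the largest within-segment first difference.

## Quality categories

Observer categories are 0 (clear consistent waveform), 1 (pulse visible
but irregular), 2 (no usable pulse). Given labelled scores, per-category
means and sample (n−1) SDs define the boundaries

$$b_{i+1,i} = \frac{\mu_{i+1}\sigma_i + \mu_i\sigma_{i+1}}
                   {\sigma_i + \sigma_{i+1}},$$

the point equidistant from both category means in per-category z-units.
The exact published form of this boundary could not be recovered from
the source material, so this interpolation — consistent with boundaries
"determined from the per-category mean and SD" — is a documented
assumption of this package, not a reconstruction. Prediction is
boundary-inclusive upward (a score exactly at a boundary takes the
better category). The promotion analysis considers only recordings whose
before- and after-scores are at least 2 dB from every boundary
(roughly 20 % of the between-boundary distance), which keeps the
predicted categories unambiguous.

## The synthetic generator

No public recordings exist for this task, so every stage is exercised on
synthetic scenes with known ground truth. A scene is a per-tile signal
model

$$x_k(t) = b_k + \alpha\, a_k\, g_k(t)\, w(t) + d_k(t) + c(t) +
  \varepsilon_k(t)$$

with baseline $b_k$, skin-tone attenuation $\alpha$, tile amplitude
$a_k$ (RMS ADC units), scheduled suppression $g_k(t)$ (transient
occlusion/movement), sinusoidal drift $d_k$ below 0.5 Hz, a shared
band-limited movement/illumination component $c(t)$ that spatial
averaging cannot remove, and white noise $\varepsilon_k$. The pulse
waveform $w$ is a unit-RMS sum of up to four harmonics (defaults 1, 0.5,
0.2), enough to give the skewed PPG morphology spectrally without a
physiological model. Frames are rendered by painting each tile's
quantised value over its 400 pixels; ADC units are 8-bit-referred, and
bit depth $b$ quantises with step $2^{8-b}$ ADC, so a 0.3-ADC-RMS pulse
vanishes at 8 bits but survives at 12.

Default cohort conditions (chosen once as a realistic heterogeneous
recording population): 30 fps, 60 s, the 62-tile midface; per-scene PR
uniform on 0.8–2.5 Hz; scene amplitude log-normal around 0.7 ADC with
per-tile log-normal spread (sdlog 0.6) and a 15 % per-tile chance of
near-total occlusion; white-noise SD 0.5–2 ADC; drift amplitude 0–3 ADC
at 0.05–0.3 Hz; common in-band noise SD 0.2–0.8 ADC; half the scenes
contain a 10–25 s disruption suppressing a third of the tiles; six
attenuation tiers (1.00, 0.85, 0.70, 0.55, 0.42, 0.30) emulate the
Fitzpatrick scale as multiplicative amplitude loss from melanin
absorption, with the tier sweep run *paired* (same base scene and seed,
attenuation varied) to isolate the attenuation effect.

The simulated observer thresholds a noisy copy of the midface score
(rating noise SD 1.5 dB; latent cut points −5 and +1 dB, placed inside
the generator's score distribution — which spans roughly −9 to +6 dB —
so all three categories are populated). This captures that human
ratings correlate with, but are not determined by, the spectral score.

What the generator does **not** emulate: geometric motion (movement is
amplitude suppression plus baseline steps, never warping), compression
artifacts, photorealistic texture, inter-channel physiology, or
correlated spatial noise beyond the single common-mode term. Passing
tests therefore demonstrate the correctness and the qualitative
behaviour of the T&A machinery, not clinical performance on real video.

## Evaluation sizes and determinism

Cohort-level checks use 200 scenes (and a 15-scene-per-tier paired
sweep), sizes at which the directional effects are far larger than their
standard errors while a full evaluation completes in about two minutes.
All generators draw from a single master seed through locally scoped RNG
state, so identical configurations reproduce byte-identical artifacts
and library code never disturbs the caller's random stream.

## Known limitations

* The boundary formula is an inference (see above); alternative
  separators (e.g. equal-likelihood points of fitted Gaussians) would
  differ when SDs are very unequal.
* The all-tile-mean PR estimate can lock onto structured in-band noise
  when no tile carries a pulse; scores are then meaningful only
  relatively.
* Full-length 720p frame stacks are deliberately not materialised in
  memory (a 60 s stack would exceed 4 GiB); frame-level code is exercised
  on smaller geometries and the tile-signal path carries the analysis.
* Segmented aggregation can look better in SNR-F terms than it is
  morphologically — selection switching interacts with baseline drift —
  which is why the transition and promotion analyses default to the
  non-segmented weighted algorithm.
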