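# tileppg

Dynamic region-of-interest selection for remote photoplethysmography
(rPPG) by **tiling and aggregation (T&A)**.

Camera-based pulse measurement extracts the cardiac signal from subtle
green-channel intensity changes in facial skin. A fixed midface region of
interest wastes signal whenever part of the face is shadowed, occluded
(glasses, facial hair) or moving. T&A instead divides the midface into
20×20-pixel tiles, scores each tile's mean-green time series with a
frequency-domain signal-to-noise metric, and combines only the best tiles
into the output pulse signal. The package is aimed at researchers
developing camera-based vital-sign pipelines who need the tile scoring,
aggregation and signal-quality-category machinery together with a fully
synthetic test bed.

## The SNR-F metric

For a tile signal sampled at `fs` Hz, the periodogram power `P(f)` is
computed after linear detrending, and the score compares the pulse band
against the rest of the physiological band:

    SNR-F = 10 log10( sum P(f), |f - PR| <= 0.15 Hz
                    / sum P(f), f in [0.5, 5] Hz outside the pulse band )

in dB, where `PR` is the pulse rate in Hz (supplied, or estimated as the
spectral peak of the all-tile mean signal). Degenerate ratios saturate at
±60 dB.

## Aggregation algorithms

Five algorithms combine the tile signals (`aggregate_tiles()`):

| method | description |
|---|---|
| `all_weighted` | weighted average of all tiles, weights ∝ 10^(dB/10) |
| `best_n` | unweighted mean of the `n` top-scoring tiles (default n = 30) |
| `best_n_weighted` | score-weighted mean of the best `n` tiles |
| `best_n_segmented` | best `n` re-selected per 10 s segment, cross-faded |
| `best_n_segmented_weighted` | segmented plus score weighting |

Observer-style quality categories (0 good, 1 usable, 2 unusable) are
modelled from labelled scores: per-category means and SDs give the
boundaries `b_21` and `b_10` via the SD-weighted interpolation
`b = (mu_i*sigma_j + mu_j*sigma_i) / (sigma_i + sigma_j)`, and
before/after T&A comparisons are summarised as transition tables, quiver
tables, and 2 dB-margin promotion predictions.

## Worked example

```r
library(tileppg)

# a synthetic 60 s recording: 40 pulsatile tiles among 22 dead ones
scene <- scene_model(fps = 30, duration_s = 60,
                     amplitude = c(runif(40, 0.5, 1.5), rep(0.02, 22)),
                     noise_sd = 1, common_noise_sd = 0.5)
pulse <- pulse_model(pr_hz = 1.2)          # 72 bpm
rec <- render_tile_signals(scene, pulse, seed = 42)
rec$matrix
#> Tile signals: 1800 frames x 62 tiles @ 30 Hz (60.0 s)

scores <- score_tiles(rec$matrix)          # one SNR-F per tile, global PR
head(scores, 3)
#>   tile_id    snrf_db pr_hz_used capped
#> 1       0 -1.3133919        1.2  FALSE
#> 2       1 -0.8566762        1.2  FALSE
#> 3       2 -0.2176809        1.2  FALSE

agg <- aggregate_tiles(rec$matrix, scores = scores,
                       config = aggregation_config("best_n_weighted", n = 30))
snrf_score(rowMeans(rec$matrix$values), 30, pr_hz = 1.2)  # no tiling
#> SNR-F: -0.230 dB (PR 1.200 Hz)
snrf_score(agg$signal, 30, pr_hz = 1.2)                   # after T&A
#> SNR-F: 2.546 dB (PR 1.200 Hz)
```

The pulse rate was recovered from the spectrum (1.2 Hz, the ground
truth), and selecting and weighting the 30 best tiles raised the output
SNR-F by about 2.8 dB over the plain midface mean — dead tiles dilute the
pulse amplitude of the mean but are excluded or down-weighted by T&A.

`run_pipeline(out_dir)` runs the whole chain (simulate → score →
aggregate → categorise → evaluate) and writes every stage artifact as
CSV/JSON. A command-line wrapper with the same stages lives at
`inst/cli/tileppg.R` (`Rscript tileppg.R simulate|tile|score|aggregate|
categorize|evaluate|run ...`).

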