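test_that("pulse waveform is zero-mean, unit-RMS, and spectrally pure", {
  w <- make_pulse_waveform(pulse_model(1.0, 1), fps = 30, duration_s = 60)
  expect_length(w, 1800)
  expect_equal(mean(w), 0, tolerance = 1e-12)
  expect_equal(sqrt(mean(w^2)), 1, tolerance = 1e-9)
  # bin-aligned single tone: all DFT power in the 1.0 Hz bin
  p <- periodogram(w, 30, detrend = 0)
  peak <- which.max(p$power)
  expect_equal(p$frequencies[peak], 1.0)
  expect_equal(p$power[peak], 1, tolerance = 1e-9)
  expect_lt(sum(p$power[-peak]), 1e-18)
})

test_that("harmonic amplitudes produce the expected power ratio", {
  w <- make_pulse_waveform(pulse_model(1.0, harmonic_amplitudes = c(1, 0.5)),
                           fps = 30, duration_s = 60)
  p <- periodogram(w, 30, detrend = 0)
  p1 <- p$power[p$frequencies == 1.0]
  p2 <- p$power[p$frequencies == 2.0]
  expect_equal(p1 / p2, 4, tolerance = 1e-9)
  expect_equal(sqrt(mean(w^2)), 1, tolerance = 1e-9)
})

test_that("invalid pulse parameters are rejected", {
  expect_error(pulse_model(0.3), "0.5-5")
  expect_error(pulse_model(1, harmonic_amplitudes = numeric(0)), "non-empty")
  expect_error(pulse_model(1, harmonic_amplitudes = c(0, 1)), "fundamental")
  expect_error(make_pulse_waveform(pulse_model(4.9, 1), fps = 8,
                                   duration_s = 10), "fps/2")
  expect_error(make_pulse_waveform(pulse_model(4.9, c(1, 0.5)), fps = 12,
                                   duration_s = 10), "Nyquist")
  expect_error(make_pulse_waveform(pulse_model(1, 1), fps = 30,
                                   duration_s = 1 / 45), "integer")
})

test_that("tile-signal rendering is deterministic and exact when noiseless", {
  ss <- small_scene(noise_sd = 0, amplitude = c(3, 1.5, 0.5, 2, 1, 0.25))
  r1 <- render_tile_signals(ss$scene, ss$pulse, seed = 4)
  r2 <- render_tile_signals(ss$scene, ss$pulse, seed = 4)
  expect_identical(r1$matrix$values, r2$matrix$values)
  # noiseless, driftless tiles are exact scaled/shifted waveform copies
  w <- make_pulse_waveform(ss$pulse, ss$scene$fps, ss$scene$duration_s)
  for (k in 1:6) {
    expect_equal(r1$matrix$values[, k],
                 ss$scene$baseline[k] + ss$scene$amplitude[k] * w,
                 tolerance = 1e-12)
  }
  # with noise, different seeds give different draws
  ssn <- small_scene(noise_sd = 1)
  n1 <- render_tile_signals(ssn$scene, ssn$pulse, seed = 4)
  n2 <- render_tile_signals(ssn$scene, ssn$pulse, seed = 5)
  expect_false(identical(n1$matrix$values, n2$matrix$values))
})

test_that("rendering does not disturb the caller's RNG stream", {
  ss <- small_scene()
  set.seed(123)
  a <- runif(1)
  set.seed(123)
  invisible(render_tile_signals(ss$scene, ss$pulse, seed = 9))
  expect_identical(runif(1), a)
})

test_that("skin-tone attenuation lowers every tile's SNR-F", {
  ss <- small_scene(amplitude = runif(6, 0.5, 2), noise_sd = 1)
  pale <- ss$scene
  dark <- ss$scene
  dark$skin_tone_attenuation <- 0.5
  s_pale <- score_tiles(render_tile_signals(pale, ss$pulse, 11)$matrix,
                        pr_hz = ss$pulse$pr_hz)
  s_dark <- score_tiles(render_tile_signals(dark, ss$pulse, 11)$matrix,
                        pr_hz = ss$pulse$pr_hz)
  expect_true(all(s_dark$snrf_db < s_pale$snrf_db))
})

test_that("quality schedule suppresses amplitude only in its window", {
  sched <- data.frame(tile_id = 0L, t_start = 5, t_end = 10, factor = 0)
  ss <- small_scene(noise_sd = 0, amplitude = rep(1, 6),
                    quality_schedule = sched)
  r <- render_tile_signals(ss$scene, ss$pulse, seed = 1)
  tt <- (seq_len(nrow(r$matrix$values)) - 1) / 30
  inside <- tt >= 5 & tt < 10
  expect_true(all(r$matrix$values[inside, 1] == ss$scene$baseline[1]))
  expect_gt(stats::sd(r$matrix$values[!inside, 1]), 0.5)
  expect_gt(stats::sd(r$matrix$values[inside, 2]), 0.5)  # other tiles untouched
})

test_that("rendered frames round-trip to the tile signals within 0.5 ADC", {
  ss <- small_scene(duration_s = 10, noise_sd = 0.5,
                    amplitude = c(2, 1, 0.5, 1.5, 0.8, 0.3))
  rs <- render_tile_signals(ss$scene, ss$pulse, seed = 3)
  rf <- render_frames(ss$scene, ss$pulse, seed = 3)
  ex <- extract_tile_signals(rf$frames, ss$scene$grid)
  expect_equal(dim(ex$values), dim(rs$matrix$values))
  expect_lt(max(abs(ex$values - rs$matrix$values)), 0.5 + 1e-9)
})

test_that("a 30 fps 60 s stack contains exactly 1800 frames", {
  sc <- scene_model(roi = rect_roi(2, 1), frame_shape = c(20L, 40L),
                    fps = 30, duration_s = 60, amplitude = 1, noise_sd = 0)
  rf <- render_frames(sc, pulse_model(1, 1), seed = 1)
  expect_identical(dim(rf$frames$pixels)[4], 1800L)
})

test_that("bit depth controls pulse detectability at sub-ADC amplitude", {
  # amplitude is RMS-scaled: 0.3 ADC RMS puts the sinusoid peak (~0.42)
  # below the 0.5 ADC rounding threshold of an 8-bit render
  mk <- function(bits) {
    sc <- scene_model(roi = rect_roi(2, 1), frame_shape = c(20L, 40L),
                      fps = 30, duration_s = 30, amplitude = 0.3,
                      baseline = 100, noise_sd = 0, bit_depth = bits)
    rf <- render_frames(sc, pulse_model(1.2, 1), seed = 1)
    ex <- extract_tile_signals(rf$frames, sc$grid)
    # mean detrend keeps a quantisation-flattened signal exactly constant
    score_tiles(ex, pr_hz = 1.2, detrend = 0)$snrf_db
  }
  s8 <- mk(8L)    # rounds away entirely at 1-ADC steps
  s12 <- mk(12L)  # 1/16-ADC steps preserve the pulse
  expect_true(all(s8 == -60))
  expect_true(all(s12 > 20))
})

test_that("frame rendering rejects a frame smaller than the ROI", {
  sc <- scene_model(roi = rect_roi(3, 2), frame_shape = c(30L, 30L),
                    fps = 30, duration_s = 5)
  expect_error(render_frames(sc, pulse_model(1, 1), 1), "smaller than the ROI")
})

test_that("cohort generation is reproducible and covers the tier range", {
  c1 <- generate_cohort(n = 6, seed = 10)
  c2 <- generate_cohort(n = 6, seed = 10)
  expect_identical(c1$manifest, c2$manifest)
  for (i in 1:6)
    expect_identical(c1$scenes[[i]]$matrix$values,
                     c2$scenes[[i]]$matrix$values)
  expect_setequal(c1$manifest$attenuation_tier, 1:6)
  expect_true(all(diff(c1$manifest$attenuation[order(
    c1$manifest$attenuation_tier)]) <= 0))
  c3 <- generate_cohort(n = 6, seed = 11)
  expect_false(identical(c1$manifest$seed, c3$manifest$seed))
})

test_that("a homogeneous scene yields near-equal tile scores", {
  sc <- scene_model(roi = rect_roi(3, 2), fps = 30, duration_s = 60,
                    amplitude = 1, noise_sd = 0.5, baseline = 100)
  r <- render_tile_signals(sc, pulse_model(1.5, 1), seed = 2)
  s <- score_tiles(r$matrix, pr_hz = 1.5)
  expect_lt(diff(range(s$snrf_db)), 3)   # sampling noise only
})

test_that("noisier tiles never score better than quieter twins (paired seeds)", {
  for (seed in 1:5) {
    ss <- small_scene(amplitude = rep(1, 6), noise_sd = 0.5)
    lo <- render_tile_signals(ss$scene, ss$pulse, seed = seed)
    hi_scene <- ss$scene
    hi_scene$noise_sd <- rep(2, 6)
    hi <- render_tile_signals(hi_scene, ss$pulse, seed = seed)
    s_lo <- score_tiles(lo$matrix, pr_hz = ss$pulse$pr_hz)
    s_hi <- score_tiles(hi$matrix, pr_hz = ss$pulse$pr_hz)
    expect_true(all(s_hi$snrf_db <= s_lo$snrf_db))
  }
})
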