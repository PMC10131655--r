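#' Harmonic pulse waveform model
#'
#' The pulse is modelled as a sum of up to a few harmonics of the pulse
#' rate with configurable relative amplitudes, which captures the skewed
#' PPG morphology (sharp systolic upstroke, slow diastolic decay) well
#' enough for spectral-band testing without a physiological model.
#'
#' @param pr_hz Pulse rate in Hz; must lie in the 0.5-5 Hz analysis band.
#' @param harmonic_amplitudes Relative amplitudes of harmonics 1..H,
#'   fundamental first. All >= 0, fundamental > 0.
#' @param phase_rad Initial phase of the fundamental in radians.
#' @return An object of class `pulse_model`.
#' @export
#' @examples
#' pulse_model(1.2)                      # 72 bpm, default morphology
#' pulse_model(1.0, harmonic_amplitudes = 1)  # pure sinusoid
pulse_model <- function(pr_hz, harmonic_amplitudes = c(1, 0.5, 0.2),
                        phase_rad = 0) {
  stopifnot(is.numeric(pr_hz), length(pr_hz) == 1)
  if (pr_hz < 0.5 || pr_hz > 5.0)
    stop("pr_hz must lie inside the 0.5-5 Hz analysis band", call. = FALSE)
  a <- as.numeric(harmonic_amplitudes)
  if (length(a) == 0 || any(a < 0) || a[1] <= 0)
    stop("harmonic_amplitudes must be non-empty, >= 0, fundamental > 0",
         call. = FALSE)
  structure(list(pr_hz = pr_hz, harmonic_amplitudes = a,
                 phase_rad = phase_rad),
            class = "pulse_model")
}

#' @export
print.pulse_model <- function(x, ...) {
  cat(sprintf("Pulse model: %.3f Hz (%.0f bpm), %d harmonic(s)\n",
              x$pr_hz, 60 * x$pr_hz, length(x$harmonic_amplitudes)))
  invisible(x)
}

#' Generate a unit-RMS pulse waveform
#'
#' @param pulse A `pulse_model`.
#' @param fps Sampling rate in Hz.
#' @param duration_s Duration in seconds; `duration_s * fps` must be a whole
#'   number of at least 2 samples.
#' @return Zero-mean numeric vector of length `fps * duration_s` with RMS
#'   exactly 1.
#' @export
make_pulse_waveform <- function(pulse, fps, duration_s) {
  stopifnot(inherits(pulse, "pulse_model"))
  n <- fps * duration_s
  if (abs(n - round(n)) > 1e-9 || n < 2)
    stop("duration_s * fps must be an integer >= 2", call. = FALSE)
  n <- as.integer(round(n))
  if (pulse$pr_hz <= 0 || pulse$pr_hz >= fps / 2)
    stop("pr_hz must lie in (0, fps/2)", call. = FALSE)
  h_max <- length(pulse$harmonic_amplitudes)
  if (h_max * pulse$pr_hz >= fps / 2)
    stop("highest harmonic exceeds the Nyquist frequency", call. = FALSE)
  tt <- (seq_len(n) - 1L) / fps
  w <- numeric(n)
  for (h in seq_len(h_max)) {
    w <- w + pulse$harmonic_amplitudes[h] *
      sin(2 * pi * h * pulse$pr_hz * tt + h * pulse$phase_rad)
  }
  w <- w - mean(w)
  w / sqrt(mean(w^2))
}

#' Synthetic facial-video scene model
#'
#' Describes one synthetic recording: geometry, timing, and per-tile signal
#' parameters. Per-tile maps (`amplitude`, `baseline`, `noise_sd`,
#' `drift_amp`, `drift_freq`) may be scalars (recycled) or vectors with one
#' entry per tile of the 20x20 grid over `roi`.
#'
#' @param roi A `midface_roi`.
#' @param frame_shape Integer `(height, width)` in pixels.
#' @param fps Frames per second; must exceed twice the 5 Hz band edge.
#' @param duration_s Recording length in seconds.
#' @param amplitude Per-tile pulsatile amplitude in ADC units (RMS of the
#'   pulsatile component; the waveform itself is unit-RMS).
#' @param baseline Per-tile mean green level, ADC units.
#' @param noise_sd Per-tile white-noise SD, ADC units.
#' @param drift_amp,drift_freq Per-tile sinusoidal baseline-drift amplitude
#'   (ADC) and frequency (Hz, below 0.5).
#' @param common_noise_sd SD of an in-band noise process shared by all
#'   tiles (lighting flicker / body movement); spatial averaging cannot
#'   remove it.
#' @param skin_tone_attenuation Scalar in (0, 1] multiplying all pulsatile
#'   amplitudes; 1 is the palest tier.
#' @param quality_schedule Optional data.frame (`tile_id`, `t_start`,
#'   `t_end`, `factor`) suppressing a tile's amplitude by `factor` during
#'   `[t_start, t_end)` seconds (models transient occlusion/movement).
#' @param bit_depth Bits per channel when rendering frames (8-16). ADC
#'   units are 8-bit-referred: depth b quantises with step `2^(8 - b)` ADC.
#' @param tile_size Tile edge in pixels (default 20).
#' @return An object of class `scene_model` (the derived `tile_grid` is
#'   attached as `$grid`).
#' @export
scene_model <- function(roi = canonical_midface_roi(),
                        frame_shape = c(720L, 1280L),
                        fps = 30, duration_s = 60,
                        amplitude = 1, baseline = 120, noise_sd = 1,
                        drift_amp = 0, drift_freq = 0.1,
                        common_noise_sd = 0,
                        skin_tone_attenuation = 1,
                        quality_schedule = NULL,
                        bit_depth = 8L, tile_size = 20L) {
  stopifnot(inherits(roi, "midface_roi"))
  if (fps <= 2 * 5.0)
    stop("fps must exceed 10 Hz (twice the 5 Hz band edge)", call. = FALSE)
  n <- fps * duration_s
  if (abs(n - round(n)) > 1e-9 || n < 2)
    stop("duration_s * fps must be an integer >= 2", call. = FALSE)
  if (skin_tone_attenuation <= 0 || skin_tone_attenuation > 1)
    stop("skin_tone_attenuation must lie in (0, 1]", call. = FALSE)
  if (bit_depth < 8 || bit_depth > 16)
    stop("bit_depth must be between 8 and 16", call. = FALSE)
  grid <- build_tile_grid(roi, tile_size)
  k <- nrow(grid$tiles)
  expand <- function(v, nm) {
    if (length(v) == 1) v <- rep(v, k)
    if (length(v) != k)
      stop(sprintf("%s must have 1 or %d entries", nm, k), call. = FALSE)
    v
  }
  if (!is.null(quality_schedule)) {
    quality_schedule <- as.data.frame(quality_schedule)
    stopifnot(all(c("tile_id", "t_start", "t_end", "factor") %in%
                    names(quality_schedule)))
  }
  if (any(drift_freq >= 0.5))
    stop("drift_freq must stay below the 0.5 Hz band edge", call. = FALSE)
  structure(list(roi = roi, grid = grid,
                 frame_shape = as.integer(frame_shape),
                 fps = fps, duration_s = duration_s,
                 amplitude = expand(amplitude, "amplitude"),
                 baseline = expand(baseline, "baseline"),
                 noise_sd = expand(noise_sd, "noise_sd"),
                 drift_amp = expand(drift_amp, "drift_amp"),
                 drift_freq = expand(drift_freq, "drift_freq"),
                 common_noise_sd = common_noise_sd,
                 skin_tone_attenuation = skin_tone_attenuation,
                 quality_schedule = quality_schedule,
                 bit_depth = as.integer(bit_depth),
                 tile_size = as.integer(tile_size)),
            class = "scene_model")
}

#' @export
print.scene_model <- function(x, ...) {
  cat(sprintf(
    "Scene: %dx%d px, %g fps, %g s, %d tiles, attenuation %.2f, %d-bit\n",
    x$frame_shape[2], x$frame_shape[1], x$fps, x$duration_s,
    nrow(x$grid$tiles), x$skin_tone_attenuation, x$bit_depth))
  invisible(x)
}

# Evaluate the generator RNG in a local, restorable state so synthesis is
# reproducible without clobbering the caller's random stream.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Render per-tile green-channel signals for a scene
#'
#' Each tile's series is `baseline + attenuation * amplitude * waveform +
#' drift + common noise + white noise`, with any scheduled amplitude
#' suppression applied. Deterministic given `seed`.
#'
#' @param scene A `scene_model`.
#' @param pulse A `pulse_model`.
#' @param seed Integer RNG seed.
#' @return A list with `matrix` (a `tile_signal_matrix`) and `truth`
#'   (ground-truth parameters: `pr_hz`, per-tile `amplitude`, `noise_sd`,
#'   `attenuation`, `rng_seed`).
#' @export
render_tile_signals <- function(scene, pulse, seed = 1L) {
  stopifnot(inherits(scene, "scene_model"), inherits(pulse, "pulse_model"))
  n <- as.integer(round(scene$fps * scene$duration_s))
  k <- nrow(scene$grid$tiles)
  w <- make_pulse_waveform(pulse, scene$fps, scene$duration_s)
  tt <- (seq_len(n) - 1L) / scene$fps
  vals <- with_seed(seed, {
    drift_phase <- stats::runif(k, 0, 2 * pi)
    common <- if (scene$common_noise_sd > 0)
      in_band_noise(n, scene$fps, scene$common_noise_sd) else numeric(n)
    noise <- matrix(stats::rnorm(n * k), nrow = n) *
      rep(scene$noise_sd, each = n)
    amp_t <- matrix(rep(scene$amplitude, each = n), nrow = n)
    qs <- scene$quality_schedule
    if (!is.null(qs) && nrow(qs) > 0) {
      for (i in seq_len(nrow(qs))) {
        col <- match(qs$tile_id[i], scene$grid$tiles$tile_id)
        if (is.na(col)) stop("quality_schedule references unknown tile_id",
                             call. = FALSE)
        sel <- tt >= qs$t_start[i] & tt < qs$t_end[i]
        amp_t[sel, col] <- amp_t[sel, col] * qs$factor[i]
      }
    }
    drift <- vapply(seq_len(k), function(j)
      scene$drift_amp[j] * sin(2 * pi * scene$drift_freq[j] * tt + drift_phase[j]),
      numeric(n))
    scene$skin_tone_attenuation * amp_t * w +
      rep(scene$baseline, each = n) + drift + common + noise
  })
  truth <- list(pr_hz = pulse$pr_hz,
                amplitude = scene$amplitude,
                noise_sd = scene$noise_sd,
                attenuation = scene$skin_tone_attenuation,
                rng_seed = as.integer(seed))
  list(matrix = tile_signal_matrix(vals, fps = scene$fps,
                                   tile_ids = scene$grid$tiles$tile_id),
       truth = truth)
}

# Gaussian noise band-limited to the 0.5-5 Hz analysis band, unit-SD scaled,
# built in the frequency domain. Emulates movement/illumination components
# that spatial averaging cannot remove.
in_band_noise <- function(n, fps, sd) {
  f <- seq(0, fps, length.out = n + 1L)[seq_len(n)]
  f <- pmin(f, fps - f)
  keep <- f >= 0.5 & f <= 5.0
  spec <- complex(real = stats::rnorm(n), imaginary = stats::rnorm(n))
  spec[!keep] <- 0
  x <- Re(stats::fft(spec, inverse = TRUE)) / n
  x <- x - mean(x)
  x / stats::sd(x) * sd
}

#' Render a synthetic RGB frame stack
#'
#' Renders frames whose green channel reproduces [render_tile_signals()]
#' within quantisation: every pixel of a tile carries the tile's signal
#' value quantised at the scene's bit depth, so the 400-pixel tile mean
#' matches the tile series within +/- 0.5 ADC. Red and blue channels and
#' non-tile pixels carry baseline only.
#'
#' @inheritParams render_tile_signals
#' @return A list with `frames` (a `frame_stack`: `pixels` array height x
#'   width x 3 x frames in ADC units, plus `fps`, `bit_depth`, `grid`) and
#'   `truth`.
#' @export
render_frames <- function(scene, pulse, seed = 1L) {
  bb <- roi_bbox(scene$roi)
  H <- scene$frame_shape[1]; W <- scene$frame_shape[2]
  if (bb["x1"] > W || bb["y1"] > H)
    stop("frame_shape smaller than the ROI", call. = FALSE)
  rs <- render_tile_signals(scene, pulse, seed)
  sig <- rs$matrix$values
  n <- nrow(sig)
  if (as.double(H) * W * 3 * n > 5e8)
    stop("frame stack too large to hold in memory; ",
         "reduce frame_shape or duration_s", call. = FALSE)
  step <- 2^(8L - scene$bit_depth)          # quantisation step in ADC
  adc_max <- (2^scene$bit_depth - 1) * step
  q <- pmin(pmax(round(sig / step) * step, 0), adc_max)
  bg <- pmin(pmax(round(mean(scene$baseline) / step) * step, 0), adc_max)
  tiles <- scene$grid$tiles
  base_q <- pmin(pmax(round(scene$baseline / step) * step, 0), adc_max)
  pixels <- array(bg, dim = c(H, W, 3L, n))
  for (k in seq_len(nrow(tiles))) {
    rows <- (tiles$y0[k] + 1L):(tiles$y0[k] + tiles$h[k])
    cols <- (tiles$x0[k] + 1L):(tiles$x0[k] + tiles$w[k])
    pixels[rows, cols, 1L, ] <- base_q[k]
    pixels[rows, cols, 3L, ] <- base_q[k]
    pixels[rows, cols, 2L, ] <-
      rep(q[, k], each = length(rows) * length(cols))
  }
  frames <- structure(list(pixels = pixels, fps = scene$fps,
                           bit_depth = scene$bit_depth, grid = scene$grid),
                      class = "frame_stack")
  list(frames = frames, truth = rs$truth)
}

#' @export
print.frame_stack <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("Frame stack: %d frames of %dx%d px, %d-bit, %g fps\n",
              d[4], d[2], d[1], x$bit_depth, x$fps))
  invisible(x)
}

#' Default synthetic-cohort configuration
#'
#' Parameter ranges emulating a heterogeneous midface recording cohort:
#' 30 fps, 60 s scenes over the canonical 62-tile ROI; per-scene pulse rate
#' uniform over 0.8-2.5 Hz (48-150 bpm); log-normal tile amplitudes around
#' 0.7 ADC with a 15% chance per tile of near-total occlusion (facial hair,
#' glasses); white-noise SD 0.5-2 ADC; sub-band drift; shared in-band
#' movement noise; and an optional transient mid-recording disruption that
#' suppresses a random third of the tiles. Attenuation tiers 1-6 emulate
#' the Fitzpatrick scale via decreasing pulsatile amplitude.
#'
#' @param duration_s Scene length in seconds (default 60).
#' @param fps Frames per second (default 30).
#' @return A named list of generator parameters, suitable for
#'   [generate_cohort()].
#' @export
cohort_config <- function(duration_s = 60, fps = 30) {
  list(
    fps = fps, duration_s = duration_s,
    pr_range = c(0.8, 2.5),
    harmonics = c(1, 0.5, 0.2),
    amplitude_meanlog = log(0.7), amplitude_sdlog = 0.35,
    tile_amp_sdlog = 0.6,
    occlusion_prob = 0.15, occlusion_factor = 0.05,
    baseline_range = c(80, 160),
    noise_sd_range = c(0.5, 2),
    drift_amp_range = c(0, 3), drift_freq_range = c(0.05, 0.3),
    common_noise_sd_range = c(0.2, 0.8),
    disruption_prob = 0.5, disruption_frac = 1 / 3,
    disruption_factor = 0.1, disruption_len_range = c(10, 25),
    attenuation_tiers = c(1.00, 0.85, 0.70, 0.55, 0.42, 0.30)
  )
}

# Draw one scene + pulse from the cohort configuration. Scene-level
# parameters are drawn from the per-scene RNG stream (seeded upstream).
draw_scene <- function(config, tier, roi, tile_count) {
  pr <- stats::runif(1, config$pr_range[1], config$pr_range[2])
  pulse <- pulse_model(pr, config$harmonics,
                       phase_rad = stats::runif(1, 0, 2 * pi))
  base_amp <- stats::rlnorm(1, config$amplitude_meanlog, config$amplitude_sdlog)
  amp <- base_amp * stats::rlnorm(tile_count, 0, config$tile_amp_sdlog)
  occl <- stats::runif(tile_count) < config$occlusion_prob
  amp[occl] <- amp[occl] * config$occlusion_factor
  schedule <- NULL
  if (stats::runif(1) < config$disruption_prob) {
    hit <- which(stats::runif(tile_count) < config$disruption_frac)
    if (length(hit) > 0) {
      len <- stats::runif(1, config$disruption_len_range[1],
                          config$disruption_len_range[2])
      t0 <- stats::runif(1, 0, config$duration_s - len)
      schedule <- data.frame(tile_id = hit - 1L, t_start = t0,
                             t_end = t0 + len,
                             factor = config$disruption_factor)
    }
  }
  scene <- scene_model(
    roi = roi, fps = config$fps, duration_s = config$duration_s,
    amplitude = amp,
    baseline = stats::runif(tile_count, config$baseline_range[1],
                            config$baseline_range[2]),
    noise_sd = stats::runif(tile_count, config$noise_sd_range[1],
                            config$noise_sd_range[2]),
    drift_amp = stats::runif(tile_count, config$drift_amp_range[1],
                             config$drift_amp_range[2]),
    drift_freq = stats::runif(tile_count, config$drift_freq_range[1],
                              config$drift_freq_range[2]),
    common_noise_sd = stats::runif(1, config$common_noise_sd_range[1],
                                   config$common_noise_sd_range[2]),
    skin_tone_attenuation = config$attenuation_tiers[tier],
    quality_schedule = schedule)
  list(scene = scene, pulse = pulse)
}

#' Generate a synthetic cohort of tile-signal recordings
#'
#' Draws `n` scenes spanning the configured ranges of pulse rate, tile
#' amplitude heterogeneity, noise, drift and attenuation tier, and renders
#' their tile signals. Attenuation tiers are assigned round-robin unless
#' `tiers` is given. Fully reproducible from `(config, n, seed)`.
#'
#' @param config Generator parameters, see [cohort_config()].
#' @param n Number of scenes (subjects).
#' @param seed Integer master seed; per-scene seeds are derived from it.
#' @param roi ROI shared by all scenes (default the canonical 62-tile mask).
#' @param tiers Optional integer vector (length `n`, values 1-6) fixing each
#'   scene's attenuation tier.
#' @param out_dir Optional directory; when given, per-scene signal CSVs and
#'   a `manifest.csv` are written there.
#' @return A list with `manifest` (data.frame: `subject`, `seed`, `pr_hz`,
#'   `attenuation_tier`, `attenuation`, `mean_amplitude`, `mean_noise_sd`,
#'   `file`) and `scenes` (list of `render_tile_signals()` results).
#' @export
generate_cohort <- function(config = cohort_config(), n = 10, seed = 1L,
                            roi = canonical_midface_roi(), tiers = NULL,
                            out_dir = NULL) {
  stopifnot(n >= 1)
  n_tiers <- length(config$attenuation_tiers)
  if (is.null(tiers)) tiers <- ((seq_len(n) - 1L) %% n_tiers) + 1L
  stopifnot(length(tiers) == n, all(tiers %in% seq_len(n_tiers)))
  grid <- build_tile_grid(roi)
  k <- nrow(grid$tiles)
  scene_seeds <- with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
  scenes <- vector("list", n)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    sp <- with_seed(scene_seeds[i], draw_scene(config, tiers[i], roi, k))
    rendered <- render_tile_signals(sp$scene, sp$pulse, seed = scene_seeds[i])
    scenes[[i]] <- c(rendered, list(scene = sp$scene, pulse = sp$pulse))
    file <- NA_character_
    if (!is.null(out_dir)) {
      file <- sprintf("subject_%03d_signals.csv", i)   # relative to out_dir
      write_signals(rendered$matrix, file.path(out_dir, file))
    }
    rows[[i]] <- data.frame(
      subject = i, seed = scene_seeds[i], pr_hz = sp$pulse$pr_hz,
      attenuation_tier = tiers[i],
      attenuation = sp$scene$skin_tone_attenuation,
      mean_amplitude = mean(sp$scene$amplitude),
      mean_noise_sd = mean(sp$scene$noise_sd),
      file = file)
  }
  manifest <- do.call(rbind, rows)
  if (!is.null(out_dir))
    utils::write.csv(manifest, file.path(out_dir, "manifest.csv"),
                     row.names = FALSE)
  list(manifest = manifest, scenes = scenes)
}
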