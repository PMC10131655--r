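# Independent brute-force oracle for the SNR-F metric: explicit DFT
# summation over band bins, no FFT, no shared code with the implementation.
snrf_oracle <- function(x, fps, pr_hz, band_lo = 0.5, band_hi = 5,
                        halfwidth = 0.15, detrend = 1, cap = 60) {
  n <- length(x)
  # polynomial detrend by explicit least squares on [0, 1]
  tt <- (seq_len(n)) / n
  if (detrend >= 0) {
    X <- vapply(0:detrend, function(p) tt^p, numeric(n))
    beta <- solve(crossprod(X), crossprod(X, x))
    x <- x - as.vector(X %*% beta)
  }
  idx <- 0:(n - 1)
  half <- floor(n / 2)
  p_pulse <- p_resid <- 0
  lo <- max(pr_hz - halfwidth, band_lo)
  hi <- min(pr_hz + halfwidth, band_hi)
  for (j in seq_len(half)) {
    f <- j * fps / n
    if (f < band_lo || f > band_hi) next
    re <- sum(x * cos(2 * pi * j * idx / n))
    im <- sum(x * sin(2 * pi * j * idx / n))
    p <- 2 * (re^2 + im^2) / n^2
    if (n %% 2 == 0 && j == half) p <- p / 2
    if (f >= lo && f <= hi) p_pulse <- p_pulse + p else p_resid <- p_resid + p
  }
  if (p_resid == 0) return(cap)
  if (p_pulse == 0) return(-cap)
  max(min(10 * log10(p_pulse / p_resid), cap), -cap)
}

# Small rectangular ROI tiling into an nx x ny grid of 20x20 tiles.
rect_roi <- function(nx, ny, tile = 20L, x0 = 0L, y0 = 0L) {
  midface_roi(data.frame(x0 = x0, y0 = y0, w = nx * tile, h = ny * tile))
}

# A small heterogeneous scene: `k` tiles (kx x ky rectangle), a few clean
# tiles among noisy ones. Returns the scene and its pulse model.
small_scene <- function(kx = 3, ky = 2, duration_s = 30, fps = 30,
                        amplitude = NULL, noise_sd = 1, pr = 1.2, ...) {
  k <- kx * ky
  if (is.null(amplitude)) amplitude <- c(2, rep(0.05, k - 1))
  list(scene = scene_model(roi = rect_roi(kx, ky),
                           frame_shape = c(ky * 20L, kx * 20L),
                           fps = fps, duration_s = duration_s,
                           amplitude = amplitude, noise_sd = noise_sd, ...),
       pulse = pulse_model(pr, harmonic_amplitudes = 1))
}
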