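#' Map per-tile SNR-F scores to normalised aggregation weights
#'
#' dB scores can be negative, so they cannot be used as weights directly.
#' The default `"linear_power"` mode converts each score back to the power
#' domain, `w_k` proportional to `10^(dB_k / 10)`, which is non-negative and
#' order-preserving. `"rank"` weights by the score's rank and
#' `"min_shift"` by the score's offset above the minimum.
#'
#' @param scores Numeric vector of per-tile dB scores (finite / capped).
#' @param mode One of `"linear_power"`, `"rank"`, `"min_shift"`.
#' @return Numeric weights, non-negative, summing to 1.
#' @export
#' @examples
#' weights_from_scores(c(0, -10))   # 10/11, 1/11
weights_from_scores <- function(scores, mode = c("linear_power", "rank",
                                                 "min_shift")) {
  mode <- match.arg(mode)
  if (length(scores) == 0)
    stop("scores must contain at least one value", call. = FALSE)
  if (!all(is.finite(scores)))
    stop("scores must be finite (cap them first)", call. = FALSE)
  w <- switch(mode,
    linear_power = 10^(scores / 10),
    rank = rank(scores, ties.method = "average"),
    min_shift = scores - min(scores))
  if (sum(w) == 0) w <- rep(1, length(scores))   # all-equal min_shift case
  w / sum(w)
}

#' Aggregation configuration
#'
#' @param method One of `"all_weighted"`, `"best_n"`, `"best_n_weighted"`,
#'   `"best_n_segmented"`, `"best_n_segmented_weighted"`.
#' @param n Number of top-scoring tiles to keep (default 30, about half of
#'   the 62-tile midface).
#' @param segment_s Segment length in seconds for segmented methods
#'   (default 10, i.e. 6 segments of a 60 s recording).
#' @param overlap_s Cross-fade length at segment boundaries in seconds
#'   (default 2).
#' @param weight_mode Score-to-weight mapping, see [weights_from_scores()].
#' @param pr_per_segment Re-estimate the pulse rate per segment instead of
#'   reusing the recording-level estimate (default FALSE).
#' @return An object of class `aggregation_config`.
#' @export
aggregation_config <- function(method = c("best_n_weighted", "all_weighted",
                                          "best_n", "best_n_segmented",
                                          "best_n_segmented_weighted"),
                               n = 30L, segment_s = 10, overlap_s = 2,
                               weight_mode = "linear_power",
                               pr_per_segment = FALSE) {
  method <- match.arg(method)
  if (n < 1) stop("n must be >= 1", call. = FALSE)
  if (overlap_s < 0 || overlap_s >= segment_s)
    stop("overlap_s must satisfy 0 <= overlap_s < segment_s", call. = FALSE)
  structure(list(method = method, n = as.integer(n), segment_s = segment_s,
                 overlap_s = overlap_s, weight_mode = weight_mode,
                 pr_per_segment = pr_per_segment),
            class = "aggregation_config")
}

# Top-n selection with deterministic tie-breaking: higher score first,
# lower tile_id on ties.
select_best_n <- function(scores, tile_ids, n) {
  if (n > length(scores))
    stop("n exceeds the number of tiles", call. = FALSE)
  ord <- order(-scores, tile_ids)
  sort(ord[seq_len(n)])
}

#' Aggregate tile signals into a single output pulse signal
#'
#' Implements the five tiling-and-aggregation algorithms: a weighted
#' average of all tiles, the unweighted and weighted mean of the best-n
#' tiles, and their time-segmented variants in which tiles are re-scored
#' and re-selected per segment and the per-segment aggregates are
#' recombined with a linear cross-fade. All selections use the SNR-F score
#' at a single recording-level pulse rate.
#'
#' @param matrix A `tile_signal_matrix`.
#' @param scores Optional per-tile score table from [score_tiles()]
#'   (columns `tile_id`, `snrf_db`); computed on the fly when `NULL`.
#'   Ignored by segmented methods, which score per segment.
#' @param config An `aggregation_config`.
#' @param band A `band_config` used when (re-)scoring.
#' @param pr_hz Pulse rate in Hz or `"auto"`.
#' @return An object of class `aggregation_result` with `signal` (numeric,
#'   same length and fps as the input), `selections` (per-segment
#'   data.frames of `tile_id`, `weight`), `segments` (frame ranges), `fps`,
#'   and the `config` echo.
#' @export
aggregate_tiles <- function(matrix, scores = NULL,
                            config = aggregation_config(),
                            band = band_config(), pr_hz = "auto") {
  stopifnot(inherits(matrix, "tile_signal_matrix"),
            inherits(config, "aggregation_config"))
  segmented <- config$method %in% c("best_n_segmented",
                                    "best_n_segmented_weighted")
  if (segmented)
    return(aggregate_segmented(matrix, config, band, pr_hz))

  if (is.null(scores))
    scores <- score_tiles(matrix, band = band, pr_hz = pr_hz)
  if (!identical(as.integer(scores$tile_id), matrix$tile_ids))
    stop("scores are not aligned to the matrix tile ids", call. = FALSE)
  s <- scores$snrf_db
  ids <- matrix$tile_ids
  sel <- switch(config$method,
    all_weighted = seq_along(ids),
    best_n = ,
    best_n_weighted = select_best_n(s, ids, config$n))
  w <- if (config$method == "best_n") {
    rep(1 / length(sel), length(sel))
  } else {
    weights_from_scores(s[sel], config$weight_mode)
  }
  signal <- as.vector(matrix$values[, sel, drop = FALSE] %*% w)
  selection <- data.frame(tile_id = ids[sel], weight = w)
  structure(list(signal = signal,
                 selections = list(selection),
                 segments = data.frame(start = 1L, end = nrow(matrix$values)),
                 fps = matrix$fps, config = config,
                 pr_hz_used = scores$pr_hz_used[1]),
            class = "aggregation_result")
}

# Partition frames into segments of segment_s seconds; a trailing segment
# shorter than 2 s is merged into its neighbour.
segment_frames <- function(n_frames, fps, segment_s) {
  if (segment_s * fps < 2 * fps)
    stop("segments must be at least 2 s long", call. = FALSE)
  n_seg <- max(1L, ceiling(n_frames / (segment_s * fps)))
  bounds <- round(seq(0, n_frames, length.out = n_seg + 1L))
  # equal-length cut at segment_s where possible
  bounds <- c(round((0:(n_seg - 1L)) * segment_s * fps), n_frames)
  if (n_seg > 1 && (bounds[n_seg + 1L] - bounds[n_seg]) < 2 * fps) {
    bounds <- bounds[-n_seg]               # merge short tail into neighbour
    n_seg <- n_seg - 1L
  }
  data.frame(start = bounds[-length(bounds)] + 1L, end = bounds[-1])
}

aggregate_segmented <- function(matrix, config, band, pr_hz) {
  v <- matrix$values
  fps <- matrix$fps
  ids <- matrix$tile_ids
  n_frames <- nrow(v)
  segs <- segment_frames(n_frames, fps, config$segment_s)
  n_seg <- nrow(segs)
  weighted <- config$method == "best_n_segmented_weighted"

  if (identical(pr_hz, "auto") && !config$pr_per_segment) {
    pr_hz <- estimate_pulse_rate(periodogram(rowMeans(v), fps), band)
  }

  selections <- vector("list", n_seg)
  offsets <- numeric(n_seg)                 # per-segment DC removed
  coef_mat <- matrix(0, nrow = length(ids), ncol = n_seg)
  for (s in seq_len(n_seg)) {
    rows <- segs$start[s]:segs$end[s]
    sub <- tile_signal_matrix(v[rows, , drop = FALSE], fps, ids)
    sc <- score_tiles(sub, band = band,
                      pr_hz = if (config$pr_per_segment) "auto" else pr_hz)
    sel <- select_best_n(sc$snrf_db, ids, config$n)
    w <- if (weighted) weights_from_scores(sc$snrf_db[sel], config$weight_mode)
         else rep(1 / length(sel), length(sel))
    coef_mat[sel, s] <- w
    offsets[s] <- sum(w * colMeans(v[rows, sel, drop = FALSE]))
    selections[[s]] <- data.frame(tile_id = ids[sel], weight = w)
  }

  # Each segment's aggregate y_s(t) = sum_k w_ks x_k(t) - offset_s is defined
  # for every t, so cross-fading blends neighbouring segment aggregates over
  # a window of overlap_s centred on each boundary.
  seg_sig <- v %*% coef_mat                 # n_frames x n_seg
  seg_sig <- sweep(seg_sig, 2, offsets)
  mix <- matrix(0, nrow = n_frames, ncol = n_seg)
  for (s in seq_len(n_seg)) mix[segs$start[s]:segs$end[s], s] <- 1
  half <- floor(config$overlap_s * fps / 2)
  if (half > 0 && n_seg > 1) {
    for (s in seq_len(n_seg - 1L)) {
      b <- segs$end[s]                      # boundary between s and s+1
      win <- max(1L, b - half + 1L):min(n_frames, b + half)
      alpha <- seq(0, 1, length.out = length(win) + 2L)[-c(1L, length(win) + 2L)]
      mix[win, ] <- 0
      mix[win, s] <- 1 - alpha
      mix[win, s + 1L] <- alpha
    }
  }
  signal <- rowSums(seg_sig * mix)
  # restore the DC level that centering removed, as its time-average
  dc <- as.vector(mix %*% offsets)
  signal <- signal + mean(dc)
  structure(list(signal = signal, selections = selections, segments = segs,
                 fps = fps, config = config,
                 pr_hz_used = if (identical(pr_hz, "auto")) NA_real_ else pr_hz),
            class = "aggregation_result")
}

#' @export
print.aggregation_result <- function(x, ...) {
  cat(sprintf("T&A output: method %s, %d frames @ %g Hz, %d segment(s)\n",
              x$config$method, length(x$signal), x$fps, nrow(x$segments)))
  invisible(x)
}

#' Run every aggregation method plus the no-tiling baseline
#'
#' Convenience wrapper used in cohort evaluation: scores the tiles once,
#' runs all five aggregation algorithms, and scores each output (and the
#' plain all-tile mean, the "no tiling" baseline) at the same pulse rate.
#'
#' @param matrix A `tile_signal_matrix`.
#' @param band A `band_config`.
#' @param pr_hz Pulse rate or `"auto"` (recording-level estimate).
#' @param n Best-n tile count (default 30).
#' @param segment_s,overlap_s Segmentation parameters.
#' @return A data.frame with columns `method` (including `"no_tiling"`) and
#'   `snrf_db` of the corresponding output signal.
#' @export
evaluate_methods <- function(matrix, band = band_config(), pr_hz = "auto",
                             n = 30L, segment_s = 10, overlap_s = 2) {
  fps <- matrix$fps
  if (identical(pr_hz, "auto"))
    pr_hz <- estimate_pulse_rate(periodogram(rowMeans(matrix$values), fps),
                                 band)
  scores <- score_tiles(matrix, band = band, pr_hz = pr_hz)
  methods <- c("all_weighted", "best_n", "best_n_weighted",
               "best_n_segmented", "best_n_segmented_weighted")
  out <- vapply(methods, function(m) {
    cfg <- aggregation_config(method = m, n = n, segment_s = segment_s,
                              overlap_s = overlap_s)
    agg <- aggregate_tiles(matrix, scores = scores, config = cfg,
                           band = band, pr_hz = pr_hz)
    snrf_score(agg$signal, fps, band = band, pr_hz = pr_hz)$value_db
  }, numeric(1))
  baseline <- snrf_score(rowMeans(matrix$values), fps, band = band,
                         pr_hz = pr_hz)$value_db
  data.frame(method = c("no_tiling", methods),
             snrf_db = c(baseline, unname(out)),
             row.names = NULL)
}
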