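test_that("score-to-weight mappings are normalized and order-preserving", {
  expect_equal(weights_from_scores(c(3, 3, 3)), rep(1 / 3, 3))
  # hand-computed: 10^0 : 10^-1 normalized
  expect_equal(weights_from_scores(c(0, -10)), c(10 / 11, 1 / 11),
               tolerance = 1e-12)
  w <- weights_from_scores(c(60, 0, -5))
  expect_gt(w[1], 1 - 1e-5)
  expect_equal(sum(w), 1)
  for (mode in c("linear_power", "rank", "min_shift")) {
    w <- weights_from_scores(c(-8, 2, -3), mode = mode)
    expect_equal(sum(w), 1)
    expect_true(all(w >= 0))
    expect_identical(order(w), order(c(-8, 2, -3)))
  }
  expect_equal(weights_from_scores(c(1, 1), mode = "min_shift"), c(0.5, 0.5))
  expect_error(weights_from_scores(numeric(0)), "at least one")
})

make_matrix <- function(seed = 3, k = 6, amplitude = c(2, rep(0.05, 5)),
                        duration_s = 30) {
  ss <- small_scene(amplitude = amplitude, duration_s = duration_s)
  render_tile_signals(ss$scene, ss$pulse, seed = seed)$matrix
}

test_that("all-tile weighted average reduces to the plain mean when scores tie", {
  m <- make_matrix()
  eq <- data.frame(tile_id = m$tile_ids, snrf_db = rep(-3, 6),
                   pr_hz_used = 1.2, capped = FALSE)
  agg <- aggregate_tiles(m, scores = eq,
                         config = aggregation_config("all_weighted"))
  expect_equal(agg$signal, rowMeans(m$values), tolerance = 1e-12)
  # single-tile matrix: identity
  m1 <- tile_signal_matrix(m$values[, 1, drop = FALSE], fps = 30)
  s1 <- score_tiles(m1, pr_hz = 1.2)
  a1 <- aggregate_tiles(m1, scores = s1,
                        config = aggregation_config("all_weighted"))
  expect_equal(a1$signal, m$values[, 1], tolerance = 1e-12)
})

test_that("weighting all tiles beats the plain mean with one clean tile", {
  m <- make_matrix()
  sc <- score_tiles(m, pr_hz = 1.2)
  agg <- aggregate_tiles(m, scores = sc,
                         config = aggregation_config("all_weighted"))
  s_agg <- snrf_score(agg$signal, 30, pr_hz = 1.2)$value_db
  s_mean <- snrf_score(rowMeans(m$values), 30, pr_hz = 1.2)$value_db
  expect_gte(s_agg, s_mean)
})

test_that("best-n degenerate cases collapse to mean and argmax", {
  m <- make_matrix()
  sc <- score_tiles(m, pr_hz = 1.2)
  all_n <- aggregate_tiles(m, scores = sc,
                           config = aggregation_config("best_n", n = 6))
  expect_equal(all_n$signal, rowMeans(m$values), tolerance = 1e-12)
  best1 <- aggregate_tiles(m, scores = sc,
                           config = aggregation_config("best_n", n = 1))
  k_best <- which.max(sc$snrf_db)
  expect_equal(best1$signal, m$values[, k_best], tolerance = 1e-12)
  # 1 clean + noise tiles, n = 1: output score equals the clean tile's and
  # exceeds the all-tile mean's
  s_b1 <- snrf_score(best1$signal, 30, pr_hz = 1.2)$value_db
  expect_equal(s_b1, sc$snrf_db[k_best], tolerance = 1e-9)
  expect_gt(s_b1, snrf_score(rowMeans(m$values), 30, pr_hz = 1.2)$value_db)
  expect_error(aggregate_tiles(m, scores = sc,
                               config = aggregation_config("best_n", n = 7)),
               "exceeds")
})

test_that("best-n tie-breaking selects lower tile ids deterministically", {
  m <- make_matrix()
  tied <- data.frame(tile_id = m$tile_ids, snrf_db = rep(0, 6),
                     pr_hz_used = 1.2, capped = FALSE)
  agg <- aggregate_tiles(m, scores = tied,
                         config = aggregation_config("best_n", n = 3))
  expect_identical(agg$selections[[1]]$tile_id, m$tile_ids[1:3])
})

test_that("best-n weighted reduces to best-n under tied scores and at n = 1", {
  m <- make_matrix()
  tied <- data.frame(tile_id = m$tile_ids, snrf_db = rep(-2, 6),
                     pr_hz_used = 1.2, capped = FALSE)
  a <- aggregate_tiles(m, scores = tied,
                       config = aggregation_config("best_n_weighted", n = 4))
  b <- aggregate_tiles(m, scores = tied,
                       config = aggregation_config("best_n", n = 4))
  expect_equal(a$signal, b$signal, tolerance = 1e-12)
  sc <- score_tiles(m, pr_hz = 1.2)
  a1 <- aggregate_tiles(m, scores = sc,
                        config = aggregation_config("best_n_weighted", n = 1))
  b1 <- aggregate_tiles(m, scores = sc,
                        config = aggregation_config("best_n", n = 1))
  expect_equal(a1$signal, b1$signal, tolerance = 1e-12)
})

test_that("stationary scenes collapse segmented to non-segmented", {
  # noiseless construction with time-constant, strictly ordered tile
  # quality: pulse at 1.0 Hz plus a fixed 3.0 Hz interference tone, both
  # bin-aligned in every 10 s segment, so each segment scores and selects
  # identically
  tt <- (0:1799) / 30
  w <- sin(2 * pi * 1.0 * tt)
  interf <- sin(2 * pi * 3.0 * tt)
  amps <- c(3, 2, 1.5, 1, 0.5, 0.25)
  vals <- vapply(seq_along(amps),
                 function(k) 100 + amps[k] * w + 0.5 * interf,
                 numeric(1800))
  m <- tile_signal_matrix(vals, fps = 30)
  seg <- aggregate_tiles(m, config = aggregation_config("best_n_segmented",
                                                        n = 3, overlap_s = 2),
                         pr_hz = 1.0)
  sc <- score_tiles(m, pr_hz = 1.0)
  non <- aggregate_tiles(m, scores = sc,
                         config = aggregation_config("best_n", n = 3),
                         pr_hz = 1.0)
  expect_identical(nrow(seg$segments), 6L)
  for (s in seg$selections)
    expect_identical(s$tile_id, seg$selections[[1]]$tile_id)
  expect_equal(seg$signal - mean(seg$signal), non$signal - mean(non$signal),
               tolerance = 1e-9)
})

test_that("segmented selection follows time-varying tile quality", {
  # tile 0 clean in the first half, tile 1 clean in the second half
  sched <- data.frame(tile_id = c(0L, 1L), t_start = c(30, 0),
                      t_end = c(60, 30), factor = 0)
  sc <- scene_model(roi = rect_roi(2, 1), fps = 30, duration_s = 60,
                    amplitude = c(2, 2), noise_sd = 0.8,
                    quality_schedule = sched)
  p <- pulse_model(1.2, 1)
  m <- render_tile_signals(sc, p, seed = 9)$matrix
  seg <- aggregate_tiles(m, config = aggregation_config(
    "best_n_segmented", n = 1, segment_s = 10, overlap_s = 2), pr_hz = 1.2)
  chosen <- vapply(seg$selections, function(s) s$tile_id, integer(1))
  expect_identical(chosen[1:3], rep(0L, 3))
  expect_identical(chosen[4:6], rep(1L, 3))
  non <- aggregate_tiles(m, scores = score_tiles(m, pr_hz = 1.2),
                         config = aggregation_config("best_n", n = 1),
                         pr_hz = 1.2)
  expect_gt(snrf_score(seg$signal, 30, pr_hz = 1.2)$value_db,
            snrf_score(non$signal, 30, pr_hz = 1.2)$value_db)
})

test_that("zero overlap concatenates per-segment aggregates exactly", {
  ss <- small_scene(amplitude = runif(6, 0.3, 2), duration_s = 60)
  m <- render_tile_signals(ss$scene, ss$pulse, seed = 12)$matrix
  seg <- aggregate_tiles(m, config = aggregation_config(
    "best_n_segmented_weighted", n = 3, segment_s = 10, overlap_s = 0),
    pr_hz = 1.2)
  # rebuild each segment by hand from its recorded selection
  offs <- numeric(nrow(seg$segments))
  for (s in seq_len(nrow(seg$segments))) {
    rows <- seg$segments$start[s]:seg$segments$end[s]
    sel <- seg$selections[[s]]
    cols <- match(sel$tile_id, m$tile_ids)
    sub <- m$values[rows, cols, drop = FALSE]
    offs[s] <- sum(sel$weight * colMeans(sub))
    expected <- as.vector(sub %*% sel$weight) - offs[s]
    got <- seg$signal[rows]
    expect_equal(got - mean(got), expected - mean(expected), tolerance = 1e-9)
  }
})

test_that("cross-fade bounds boundary steps by within-segment variation", {
  ss <- small_scene(amplitude = runif(6, 0.2, 2), duration_s = 60)
  m <- render_tile_signals(ss$scene, ss$pulse, seed = 20)$matrix
  seg <- aggregate_tiles(m, config = aggregation_config(
    "best_n_segmented", n = 2, segment_s = 10, overlap_s = 2), pr_hz = 1.2)
  d <- abs(diff(seg$signal))
  boundary_frames <- seg$segments$end[-nrow(seg$segments)]
  interior <- setdiff(seq_along(d), boundary_frames)
  expect_lte(max(d[boundary_frames]), max(d[interior]))
})

test_that("aggregation is equivariant under tile permutation", {
  ss <- small_scene(amplitude = runif(6, 0.2, 2))
  m <- render_tile_signals(ss$scene, ss$pulse, seed = 5)$matrix
  perm <- c(4, 1, 6, 2, 5, 3)
  mp <- tile_signal_matrix(m$values[, perm], fps = 30,
                           tile_ids = m$tile_ids[perm])
  for (method in c("all_weighted", "best_n_weighted", "best_n_segmented")) {
    cfg <- aggregation_config(method, n = 3, segment_s = 10)
    a <- aggregate_tiles(m, config = cfg, pr_hz = 1.2)
    b <- aggregate_tiles(mp, config = cfg, pr_hz = 1.2)
    expect_equal(a$signal, b$signal, tolerance = 1e-10)
  }
})

test_that("outputs are convex combinations of tile samples (to offset)", {
  ss <- small_scene(amplitude = runif(6, 0.2, 2), duration_s = 60)
  m <- render_tile_signals(ss$scene, ss$pulse, seed = 7)$matrix
  for (method in c("all_weighted", "best_n", "best_n_weighted")) {
    a <- aggregate_tiles(m, config = aggregation_config(method, n = 3),
                         pr_hz = 1.2)
    lo <- apply(m$values, 1, min)
    hi <- apply(m$values, 1, max)
    expect_true(all(a$signal >= lo - 1e-9 & a$signal <= hi + 1e-9))
    w <- a$selections[[1]]$weight
    expect_equal(sum(w), 1, tolerance = 1e-12)
    expect_true(all(w >= 0))
  }
})

test_that("misaligned or too-short inputs are rejected", {
  m <- make_matrix()
  bad <- data.frame(tile_id = rev(m$tile_ids), snrf_db = rnorm(6),
                    pr_hz_used = 1.2, capped = FALSE)
  expect_error(aggregate_tiles(m, scores = bad), "not aligned")
  expect_error(aggregation_config(segment_s = 2, overlap_s = 2), "overlap_s")
  short <- tile_signal_matrix(m$values[1:30, ], fps = 30)
  expect_error(aggregate_tiles(short, config = aggregation_config(
    "best_n_segmented", n = 2, segment_s = 1, overlap_s = 0)), "at least 2 s")
})
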