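#' Evaluate the tiling-and-aggregation pipeline on a synthetic cohort
#'
#' Generates a cohort of synthetic midface recordings, scores every scene
#' before (plain all-tile mean) and after each aggregation algorithm, fits
#' observer-category boundaries to simulated labels on the before-scores,
#' and tabulates category transitions and margin-eligible promotion
#' predictions for a chosen algorithm.
#'
#' @param n_scenes Number of synthetic recordings.
#' @param seed Master RNG seed.
#' @param config Cohort generator configuration, see [cohort_config()].
#' @param tiers Optional per-scene attenuation tiers (see
#'   [generate_cohort()]).
#' @param n_best Best-n tile count (default 30).
#' @param segment_s,overlap_s Segmentation parameters.
#' @param band A `band_config`.
#' @param transition_method Method whose outputs drive the transition and
#'   promotion analyses (default `"best_n_weighted"`).
#' @param margin_db Promotion-eligibility margin in dB (default 2).
#' @param label_thresholds,observer_sd Parameters of the simulated observer,
#'   see [simulate_observer_labels()].
#' @return A list of class `ta_cohort_eval`:
#'   `scores` (data.frame scene x method SNR-F, incl. `no_tiling`),
#'   `method_means` (named mean SNR-F per method),
#'   `fit` (the `category_fit`), `before`/`after` categories,
#'   `transitions` (a `transition_table`), `promotion`
#'   (predictions + realised changes + agreement rate), and the cohort
#'   `manifest`.
#' @export
evaluate_cohort <- function(n_scenes = 60, seed = 1L,
                            config = cohort_config(), tiers = NULL,
                            n_best = 30L, segment_s = 10, overlap_s = 2,
                            band = band_config(),
                            transition_method = "best_n_weighted",
                            margin_db = 2,
                            label_thresholds = c(-5, 1),
                            observer_sd = 1.5) {
  cohort <- generate_cohort(config, n = n_scenes, seed = seed, tiers = tiers)
  rows <- lapply(seq_len(n_scenes), function(i) {
    ev <- evaluate_methods(cohort$scenes[[i]]$matrix, band = band,
                           n = n_best, segment_s = segment_s,
                           overlap_s = overlap_s)
    stats::setNames(ev$snrf_db, ev$method)
  })
  scores <- as.data.frame(do.call(rbind, rows))
  scores$scene <- seq_len(n_scenes)
  method_means <- colMeans(scores[, setdiff(names(scores), "scene")])

  before_db <- scores$no_tiling
  after_db <- scores[[transition_method]]
  labels_before <- simulate_observer_labels(before_db, label_thresholds,
                                            observer_sd, seed = seed + 1L)
  labels_after <- simulate_observer_labels(after_db, label_thresholds,
                                           observer_sd, seed = seed + 2L)
  fit <- fit_category_boundaries(before_db, labels_before)
  trans <- transition_table(predict(fit, before_db), predict(fit, after_db))

  promo <- predict_promotion(before_db, after_db, fit, margin_db)
  realized <- labels_before - labels_after      # positive = promoted
  promo$realized_change <- realized
  elig <- promo$eligible & !is.na(promo$predicted_change)
  agreement <- if (any(elig))
    mean(promo$predicted_change[elig] == realized[elig]) else NA_real_

  structure(list(scores = scores, method_means = method_means,
                 fit = fit,
                 labels_before = labels_before, labels_after = labels_after,
                 transitions = trans,
                 promotion = list(table = promo, n_eligible = sum(elig),
                                  agreement = agreement),
                 manifest = cohort$manifest,
                 transition_method = transition_method),
            class = "ta_cohort_eval")
}

#' @export
print.ta_cohort_eval <- function(x, ...) {
  cat(sprintf("Synthetic cohort evaluation (%d scenes)\n",
              nrow(x$scores)))
  cat("Mean output SNR-F (dB) by method:\n")
  print(round(x$method_means, 3))
  cat(sprintf("\nTransitions under '%s':\n", x$transition_method))
  print(x$transitions)
  if (!is.na(x$promotion$agreement))
    cat(sprintf("Margin-eligible promotion predictions: %d, agreement %.0f%%\n",
                x$promotion$n_eligible, 100 * x$promotion$agreement))
  invisible(x)
}

#' Run the full pipeline and write all stage outputs to a directory
#'
#' Simulate -> tile-signal extraction -> scoring -> all five aggregations
#' -> category fitting -> transition/promotion evaluation, with every
#' artifact written as CSV/JSON. Re-running with the same configuration and
#' seed reproduces identical files.
#'
#' @param out_dir Output directory (created if needed).
#' @param n_scenes,seed,fps,duration_s Cohort size and recording
#'   parameters.
#' @param n_best,segment_s,overlap_s Aggregation parameters.
#' @param margin_db Promotion margin (dB).
#' @param write_scene_csv Write per-scene signal and score CSVs (default
#'   TRUE; the first scene is always written).
#' @return The `ta_cohort_eval` result, invisibly; side effect: files under
#'   `out_dir` (`manifest.csv`, per-scene `*_signals.csv` / `*_scores.csv`,
#'   `aggregate_<method>.csv` for the first scene, `method_means.csv`,
#'   `boundaries.json`, `transitions.csv`, `quiver.csv`, `run_log.json`).
#' @export
run_pipeline <- function(out_dir, n_scenes = 12, seed = 1L, fps = 30,
                         duration_s = 60, n_best = 30L, segment_s = 10,
                         overlap_s = 2, margin_db = 2,
                         write_scene_csv = TRUE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  config <- cohort_config(duration_s = duration_s, fps = fps)
  ev <- evaluate_cohort(n_scenes = n_scenes, seed = seed, config = config,
                        n_best = n_best, segment_s = segment_s,
                        overlap_s = overlap_s, margin_db = margin_db)
  cohort <- generate_cohort(config, n = n_scenes, seed = seed,
                            out_dir = if (write_scene_csv) out_dir else NULL)
  band <- band_config()
  first <- cohort$scenes[[1]]$matrix
  if (!write_scene_csv)
    write_signals(first, file.path(out_dir, "subject_001_signals.csv"))
  sc <- score_tiles(first, band = band)
  write_scores(sc, file.path(out_dir, "subject_001_scores.csv"))
  for (m in c("all_weighted", "best_n", "best_n_weighted",
              "best_n_segmented", "best_n_segmented_weighted")) {
    cfg <- aggregation_config(method = m, n = n_best,
                              segment_s = segment_s, overlap_s = overlap_s)
    agg <- aggregate_tiles(first, scores = sc, config = cfg, band = band)
    df <- data.frame(time_s = fmt_num((seq_along(agg$signal) - 1L) / agg$fps),
                     value = fmt_num(agg$signal))
    utils::write.csv(df, file.path(out_dir, sprintf("aggregate_%s.csv", m)),
                     row.names = FALSE, quote = FALSE)
  }
  utils::write.csv(
    data.frame(method = names(ev$method_means),
               mean_snrf_db = fmt_num(unname(ev$method_means))),
    file.path(out_dir, "method_means.csv"), row.names = FALSE, quote = FALSE)
  write_boundaries(ev$fit, file.path(out_dir, "boundaries.json"))
  tr <- as.data.frame(as.table(ev$transitions$counts))
  names(tr) <- c("before", "after", "count")
  utils::write.csv(tr, file.path(out_dir, "transitions.csv"),
                   row.names = FALSE, quote = FALSE)
  qv <- quiver_comparison(ev$scores$no_tiling, ev$scores[[ev$transition_method]])
  utils::write.csv(
    data.frame(rank = qv$rank, before_db = fmt_num(qv$before_db),
               after_db = fmt_num(qv$after_db),
               delta_db = fmt_num(qv$delta_db)),
    file.path(out_dir, "quiver.csv"), row.names = FALSE, quote = FALSE)
  jsonlite::write_json(
    list(package = "tileppg",
         version = as.character(utils::packageVersion("tileppg")),
         seed = seed, n_scenes = n_scenes, fps = fps,
         duration_s = duration_s, n_best = n_best, segment_s = segment_s,
         overlap_s = overlap_s, margin_db = margin_db,
         band = unclass(band)),
    file.path(out_dir, "run_log.json"), auto_unbox = TRUE, digits = NA)
  invisible(ev)
}

#' Paired skin-tone tier sweep
#'
#' Renders the same base scenes at each of the six attenuation tiers (same
#' per-scene seed, only the attenuation changes) and evaluates every
#' aggregation method per tier. The pairing isolates the attenuation
#' effect from between-scene variability.
#'
#' @param n_per_tier Base scenes per tier.
#' @param seed Master seed.
#' @param config Cohort configuration.
#' @param n_best,segment_s,overlap_s,band As in [evaluate_cohort()].
#' @return A data.frame with columns `tier`, `scene`, `method`, `snrf_db`.
#' @export
tier_sweep <- function(n_per_tier = 20, seed = 1L, config = cohort_config(),
                       n_best = 30L, segment_s = 10, overlap_s = 2,
                       band = band_config()) {
  roi <- canonical_midface_roi()
  grid <- build_tile_grid(roi)
  k <- nrow(grid$tiles)
  scene_seeds <- with_seed(seed, sample.int(.Machine$integer.max - 1L,
                                            n_per_tier))
  tiers <- seq_along(config$attenuation_tiers)
  rows <- list()
  for (i in seq_len(n_per_tier)) {
    base <- with_seed(scene_seeds[i], draw_scene(config, 1L, roi, k))
    for (tier in tiers) {
      scene <- base$scene
      scene$skin_tone_attenuation <- config$attenuation_tiers[tier]
      rendered <- render_tile_signals(scene, base$pulse,
                                      seed = scene_seeds[i])
      ev <- evaluate_methods(rendered$matrix, band = band, n = n_best,
                             segment_s = segment_s, overlap_s = overlap_s)
      ev$tier <- tier
      ev$scene <- i
      rows[[length(rows) + 1L]] <- ev
    }
  }
  out <- do.call(rbind, rows)
  out[, c("tier", "scene", "method", "snrf_db")]
}
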