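#' Fit observer-category boundaries from labelled SNR-F scores
#'
#' Observer categories are 0 (clear, consistent waveform), 1 (pulse visible
#' but irregular) and 2 (no usable pulse). Per-category means and standard
#' deviations of the SNR-F scores are computed, and the boundary between
#' adjacent categories i+1 and i is placed at the SD-weighted interpolation
#'
#' \deqn{b_{i+1,i} = \frac{\mu_{i+1}\sigma_i + \mu_i\sigma_{i+1}}
#'                        {\sigma_i + \sigma_{i+1}}}
#'
#' the point equidistant from the two category means in per-category
#' z-units. Category means must satisfy mu_0 > mu_1 > mu_2.
#'
#' @param snrf_db Numeric vector of SNR-F scores in dB.
#' @param category Integer vector of observer labels in \{0, 1, 2\},
#'   aligned with `snrf_db`.
#' @return An object of class `category_fit` with per-category statistics
#'   (`stats`: `category`, `n`, `mu`, `sigma`), boundaries `b_21` and
#'   `b_10` (dB), and the training scores.
#' @seealso [predict.category_fit()], [predict_category()]
#' @export
#' @examples
#' set.seed(1)
#' scores <- c(rnorm(50, 5, 3), rnorm(50, -2, 3), rnorm(50, -9, 3))
#' labels <- rep(c(0, 1, 2), each = 50)
#' fit <- fit_category_boundaries(scores, labels)
#' coef(fit)
fit_category_boundaries <- function(snrf_db, category) {
  stopifnot(length(snrf_db) == length(category))
  if (!all(category %in% 0:2))
    stop("categories must be 0, 1 or 2", call. = FALSE)
  if (!all(is.finite(snrf_db)))
    stop("scores must be finite", call. = FALSE)
  stats <- do.call(rbind, lapply(0:2, function(i) {
    x <- snrf_db[category == i]
    data.frame(category = i, n = length(x),
               mu = mean(x), sigma = stats::sd(x))
  }))
  if (any(stats$n < 2))
    stop("need at least 2 samples in every category", call. = FALSE)
  if (any(stats$sigma <= 0))
    stop("per-category standard deviations must be positive", call. = FALSE)
  mu <- stats$mu[match(0:2, stats$category)]
  sg <- stats$sigma[match(0:2, stats$category)]
  if (!(mu[1] > mu[2] && mu[2] > mu[3]))
    stop("non-separable labels: category means must satisfy mu_0 > mu_1 > mu_2",
         call. = FALSE)
  pair <- function(mu_lo, sg_lo, mu_hi, sg_hi)   # lo = lower-quality category
    (mu_lo * sg_hi + mu_hi * sg_lo) / (sg_lo + sg_hi)
  b_21 <- pair(mu[3], sg[3], mu[2], sg[2])
  b_10 <- pair(mu[2], sg[2], mu[1], sg[1])
  if (b_21 >= b_10)
    stop("degenerate boundaries: b_21 >= b_10", call. = FALSE)
  structure(list(stats = stats, b_21 = b_21, b_10 = b_10,
                 snrf_db = snrf_db, category = as.integer(category)),
            class = "category_fit")
}

#' @export
print.category_fit <- function(x, ...) {
  cat("Observer-category boundary fit (SNR-F, dB)\n")
  cat(sprintf("  b_2,1 = %.3f dB   b_1,0 = %.3f dB\n", x$b_21, x$b_10))
  invisible(x)
}

#' @export
summary.category_fit <- function(object, ...) {
  print(object)
  cat("\nPer-category score statistics:\n")
  print(transform(object$stats, mu = round(mu, 3), sigma = round(sigma, 3)),
        row.names = FALSE)
  invisible(object)
}

#' @export
coef.category_fit <- function(object, ...) {
  c(b_21 = object$b_21, b_10 = object$b_10)
}

#' Predict observer categories for new SNR-F scores
#'
#' @param object A `category_fit`.
#' @param newdata Numeric vector of SNR-F scores (dB); defaults to the
#'   training scores.
#' @param ... Unused.
#' @return Integer categories in \{0, 1, 2\}.
#' @export
predict.category_fit <- function(object, newdata = object$snrf_db, ...) {
  predict_category(newdata, object)
}

#' @export
plot.category_fit <- function(x, ...) {
  sp <- split(x$snrf_db, x$category)
  graphics::boxplot(rev(sp), horizontal = TRUE,
                    names = paste("cat", rev(names(sp))),
                    xlab = "SNR-F (dB)",
                    main = "SNR-F by observer category", ...)
  graphics::abline(v = c(x$b_21, x$b_10), col = "red", lty = 2)
  invisible(x)
}

#' Assign an observer category from an SNR-F score
#'
#' A score below `b_21` is predicted category 2, a score in
#' `[b_21, b_10)` category 1, and a score at or above `b_10` category 0
#' (boundaries are inclusive upward).
#'
#' @param snrf_db Numeric vector of scores in dB.
#' @param boundaries A `category_fit` or a list with `b_21` and `b_10`.
#' @return Integer vector of categories.
#' @export
predict_category <- function(snrf_db, boundaries) {
  b21 <- boundaries$b_21; b10 <- boundaries$b_10
  stopifnot(is.numeric(b21), is.numeric(b10), b21 < b10)
  ifelse(snrf_db < b21, 2L, ifelse(snrf_db < b10, 1L, 0L))
}

#' Category transition table before vs after tiling and aggregation
#'
#' @param before,after Equal-length integer vectors of categories
#'   (0 best, 2 worst).
#' @return An object of class `transition_table`: the 3x3 count matrix
#'   (rows = before, columns = after), cell percentages, and summary
#'   fractions `improved` (moved to a better category), `into_cat0`,
#'   `unchanged`, `demoted`, and `cat2_to_1`.
#' @export
transition_table <- function(before, after) {
  if (length(before) != length(after))
    stop("before and after must have the same length", call. = FALSE)
  stopifnot(all(before %in% 0:2), all(after %in% 0:2))
  counts <- table(factor(before, levels = 0:2),
                  factor(after, levels = 0:2))
  counts <- matrix(as.integer(counts), 3, 3,
                   dimnames = list(before = 0:2, after = 0:2))
  n <- length(before)
  fr <- list(improved = mean(after < before),
             into_cat0 = mean(after == 0 & before > 0),
             unchanged = mean(after == before),
             demoted = mean(after > before),
             cat2_to_1 = mean(before == 2 & after == 1))
  structure(list(counts = counts, percentages = 100 * counts / n,
                 n = n, fractions = fr),
            class = "transition_table")
}

#' @export
print.transition_table <- function(x, ...) {
  cat(sprintf("Category transitions (n = %d), rows before / cols after:\n", x$n))
  print(x$counts)
  with(x$fractions, cat(sprintf(
    "improved %.1f%% | into cat 0 %.1f%% | unchanged %.1f%% | demoted %.1f%% | 2->1 %.1f%%\n",
    100 * improved, 100 * into_cat0, 100 * unchanged, 100 * demoted,
    100 * cat2_to_1)))
  invisible(x)
}

#' Margin-based promotion prediction
#'
#' A recording is eligible for a category-change prediction only when its
#' SNR-F scores both before and after tiling-and-aggregation lie at least
#' `margin_db` (default 2 dB) from every category boundary, which keeps the
#' predicted categories unambiguous. For eligible pairs the predicted
#' change is `category(before) - category(after)` (positive = promotion).
#'
#' @param score_before,score_after Numeric vectors of SNR-F scores (dB).
#' @param boundaries A `category_fit` (or list with `b_21`, `b_10`).
#' @param margin_db Required distance from every boundary (default 2).
#' @return A data.frame with `eligible`, `cat_before`, `cat_after`, and
#'   `predicted_change` (integer; `NA` when ineligible or no change).
#' @export
predict_promotion <- function(score_before, score_after, boundaries,
                              margin_db = 2) {
  stopifnot(length(score_before) == length(score_after), margin_db > 0)
  b <- c(boundaries$b_21, boundaries$b_10)
  clear <- function(s)
    apply(abs(outer(s, b, "-")) >= margin_db, 1, all)
  eligible <- clear(score_before) & clear(score_after)
  cb <- predict_category(score_before, boundaries)
  ca <- predict_category(score_after, boundaries)
  change <- cb - ca
  change[!eligible | change == 0L] <- NA_integer_
  data.frame(eligible = eligible, cat_before = cb, cat_after = ca,
             predicted_change = change)
}

#' Ranked before/after score comparison (quiver table)
#'
#' Pairs each recording's SNR-F score before and after tiling-and-
#' aggregation and ranks the pairs by descending before-score, so that
#' score gains and losses show as deviations from a descending curve when
#' plotted. The plot method draws the corresponding arrow (quiver) display.
#'
#' @param score_before,score_after Numeric vectors of SNR-F scores (dB).
#' @return An object of class `quiver_comparison`: a data.frame with
#'   `rank`, `before_db`, `after_db`, `delta_db`, sorted by descending
#'   `before_db`.
#' @export
quiver_comparison <- function(score_before, score_after) {
  if (length(score_before) != length(score_after))
    stop("before and after must have the same length", call. = FALSE)
  ord <- order(-score_before)
  out <- data.frame(rank = seq_along(ord),
                    before_db = score_before[ord],
                    after_db = score_after[ord],
                    delta_db = score_after[ord] - score_before[ord])
  class(out) <- c("quiver_comparison", "data.frame")
  out
}

#' @export
plot.quiver_comparison <- function(x, ...) {
  ylim <- range(x$before_db, x$after_db)
  graphics::plot(x$rank, x$before_db, type = "l", ylim = ylim,
                 xlab = "rank (by score before T&A)", ylab = "SNR-F (dB)",
                 main = "SNR-F before vs after T&A", ...)
  nz <- x$delta_db != 0
  if (any(nz))
    graphics::arrows(x$rank[nz], x$before_db[nz], x$rank[nz], x$after_db[nz],
                     length = 0.04,
                     col = ifelse(x$delta_db[nz] > 0, "forestgreen", "firebrick"))
  invisible(x)
}

#' Simulate observer category labels from SNR-F scores
#'
#' Synthetic stand-in for the human observer: the label is obtained by
#' thresholding the score plus Gaussian rating noise, reflecting that
#' observers judge waveform morphology, which correlates with (but is not
#' determined by) the spectral score.
#'
#' @param snrf_db Numeric vector of scores (dB).
#' @param thresholds Length-2 numeric, the latent 2/1 and 1/0 cut points in
#'   dB (defaults -5 and 1, matching the default cohort generator's
#'   score distribution).
#' @param observer_sd SD of the rating noise in dB (default 1.5).
#' @param seed Integer RNG seed.
#' @return Integer categories in \{0, 1, 2\}.
#' @export
simulate_observer_labels <- function(snrf_db, thresholds = c(-5, 1),
                                     observer_sd = 1.5, seed = 1L) {
  stopifnot(length(thresholds) == 2, thresholds[1] < thresholds[2])
  latent <- with_seed(seed,
    snrf_db + stats::rnorm(length(snrf_db), sd = observer_sd))
  ifelse(latent < thresholds[1], 2L, ifelse(latent < thresholds[2], 1L, 0L))
}
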