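# CSV/JSON/image readers and writers. All numeric CSV output is written
# with 9 significant digits so reruns are byte-comparable.

fmt_num <- function(x) format(x, digits = 9, trim = TRUE, scientific = FALSE)

#' Write a tile-signal matrix as CSV
#'
#' Columns are `time_s` followed by `tile_<id>` in grid order; values keep
#' 9 significant digits.
#'
#' @param matrix A `tile_signal_matrix`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_signals <- function(matrix, path) {
  stopifnot(inherits(matrix, "tile_signal_matrix"))
  n <- nrow(matrix$values)
  df <- data.frame(time_s = fmt_num((seq_len(n) - 1L) / matrix$fps))
  for (j in seq_along(matrix$tile_ids))
    df[[sprintf("tile_%d", matrix$tile_ids[j])]] <- fmt_num(matrix$values[, j])
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a tile-signal matrix from CSV
#'
#' @param path CSV written by [write_signals()].
#' @param fps Sampling rate; inferred from the `time_s` column when `NULL`.
#' @return A `tile_signal_matrix`.
#' @export
read_signals <- function(path, fps = NULL) {
  df <- utils::read.csv(path, check.names = FALSE)
  if (!"time_s" %in% names(df))
    stop("malformed signal CSV: missing column 'time_s'", call. = FALSE)
  tile_cols <- grep("^tile_[0-9]+$", names(df), value = TRUE)
  if (length(tile_cols) == 0)
    stop("malformed signal CSV: no 'tile_<id>' columns", call. = FALSE)
  vals <- as.matrix(df[, tile_cols, drop = FALSE])
  if (!is.numeric(vals) || anyNA(vals)) {
    bad <- which(is.na(vals) | !is.finite(vals), arr.ind = TRUE)[1, ]
    stop(sprintf("non-numeric cell at row %d, column %s",
                 bad[1], tile_cols[bad[2]]), call. = FALSE)
  }
  if (is.null(fps)) {
    dt <- diff(df$time_s)
    if (length(dt) == 0 || any(dt <= 0))
      stop("cannot infer fps from time_s", call. = FALSE)
    fps <- round(1 / stats::median(dt), 6)
  }
  ids <- as.integer(sub("^tile_", "", tile_cols))
  tile_signal_matrix(unname(vals), fps = fps, tile_ids = ids)
}

#' Write / read a per-tile score table
#'
#' @param scores Data.frame from [score_tiles()].
#' @param path CSV path.
#' @return `path` (write) / the score data.frame (read).
#' @export
write_scores <- function(scores, path) {
  stopifnot(all(c("tile_id", "snrf_db", "pr_hz_used", "capped") %in%
                  names(scores)))
  out <- data.frame(tile_id = scores$tile_id,
                    snrf_db = fmt_num(scores$snrf_db),
                    pr_hz_used = fmt_num(scores$pr_hz_used),
                    capped = tolower(as.character(scores$capped)))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_scores
#' @export
read_scores <- function(path) {
  df <- utils::read.csv(path)
  need <- c("tile_id", "snrf_db", "pr_hz_used", "capped")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0)
    stop(sprintf("malformed score CSV: missing column '%s'", miss[1]),
         call. = FALSE)
  df$capped <- as.logical(df$capped)
  df
}

#' Write a frame stack to disk
#'
#' Writes either a multi-page TIFF (`format = "tiff"`) or a directory of
#' numbered PNG frames (`format = "png"`), plus a JSON sidecar carrying
#' `fps`, `width`, `height`, `bit_depth`, and the ROI rectangles (0-based,
#' half-open). Pixels are stored as `value / (2^bit_depth - 1)` of the
#' quantised ADC level; depths above 8 use 16-bit containers.
#'
#' @param frames A `frame_stack` from [render_frames()].
#' @param path Output TIFF file (tiff) or directory (png).
#' @param format `"tiff"` or `"png"`.
#' @param roi Optional `midface_roi` recorded in the sidecar.
#' @param seed Optional generator seed recorded in the sidecar.
#' @return `path`, invisibly.
#' @export
write_frames <- function(frames, path, format = c("tiff", "png"),
                         roi = NULL, seed = NULL) {
  format <- match.arg(format)
  stopifnot(inherits(frames, "frame_stack"))
  b <- frames$bit_depth
  step <- 2^(8L - b)
  levels <- 2^b - 1
  d <- dim(frames$pixels)
  to_unit <- function(i) frames$pixels[, , , i] / step / levels
  container_bits <- if (b <= 8) 8L else 16L
  if (format == "tiff") {
    pages <- lapply(seq_len(d[4]), to_unit)
    tiff::writeTIFF(pages, path, bits.per.sample = container_bits)
    sidecar <- sub("\\.tiff?$", ".json", path)
    if (sidecar == path) sidecar <- paste0(path, ".json")
  } else {
    dir.create(path, showWarnings = FALSE, recursive = TRUE)
    for (i in seq_len(d[4]))
      png::writePNG(to_unit(i),
                    file.path(path, sprintf("frame_%05d.png", i)),
                    dpi = NULL)
    sidecar <- file.path(path, "sidecar.json")
  }
  meta <- list(fps = frames$fps, width = d[2], height = d[1],
               bit_depth = b, n_frames = d[4], format = format)
  if (!is.null(roi)) meta$roi <- roi$rects
  if (!is.null(seed)) meta$seed <- seed
  jsonlite::write_json(meta, sidecar, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a frame stack written by [write_frames()]
#'
#' @param path TIFF file or PNG directory.
#' @param sidecar Optional sidecar JSON path (located automatically by
#'   default).
#' @return A `frame_stack` in ADC units.
#' @export
read_frames <- function(path, sidecar = NULL) {
  if (dir.exists(path)) {
    if (is.null(sidecar)) sidecar <- file.path(path, "sidecar.json")
    if (!file.exists(sidecar))
      stop("missing sidecar JSON for PNG directory", call. = FALSE)
    meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    files <- sort(list.files(path, pattern = "^frame_[0-9]+\\.png$",
                             full.names = TRUE))
    if (length(files) == 0) stop("no PNG frames found", call. = FALSE)
    pages <- lapply(files, png::readPNG)
  } else {
    if (!file.exists(path)) stop(sprintf("no such file: %s", path),
                                 call. = FALSE)
    if (is.null(sidecar)) {
      sidecar <- sub("\\.tiff?$", ".json", path)
      if (sidecar == path) sidecar <- paste0(path, ".json")
    }
    if (!file.exists(sidecar))
      stop("missing sidecar JSON for TIFF stack", call. = FALSE)
    meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    pages <- tiff::readTIFF(path, all = TRUE)
  }
  b <- meta$bit_depth
  step <- 2^(8L - b)
  levels <- 2^b - 1
  d1 <- dim(pages[[1]])
  pixels <- array(NA_real_, dim = c(d1[1], d1[2], 3L, length(pages)))
  for (i in seq_along(pages)) pixels[, , , i] <- pages[[i]] * levels * step
  grid <- NULL
  if (!is.null(meta$roi))
    grid <- build_tile_grid(midface_roi(as.data.frame(meta$roi)))
  structure(list(pixels = pixels, fps = meta$fps, bit_depth = b, grid = grid),
            class = "frame_stack")
}

#' Write / read fitted category boundaries as JSON
#'
#' @param fit A `category_fit`.
#' @param path JSON path.
#' @return `path` (write) / a list with `b_21`, `b_10` and `stats` (read).
#' @export
write_boundaries <- function(fit, path) {
  stopifnot(inherits(fit, "category_fit"))
  jsonlite::write_json(list(b_21 = fit$b_21, b_10 = fit$b_10,
                            stats = fit$stats),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_boundaries
#' @export
read_boundaries <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(obj$b_21) || is.null(obj$b_10))
    stop("malformed boundaries JSON: need b_21 and b_10", call. = FALSE)
  obj
}

#' Read a pipeline run configuration (YAML or JSON)
#'
#' The configuration mirrors [run_pipeline()]'s arguments; unknown keys are
#' rejected so typos fail loudly.
#'
#' @param path `.yaml`/`.yml` or `.json` file.
#' @return A named list of configuration values.
#' @export
read_run_config <- function(path) {
  cfg <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
         else jsonlite::read_json(path, simplifyVector = TRUE)
  known <- c("n_scenes", "seed", "fps", "duration_s", "tile_size", "n_best",
             "segment_s", "overlap_s", "band_lo", "band_hi",
             "pulse_halfwidth", "margin_db", "pr_hz", "label_thresholds",
             "observer_sd", "write_frames")
  unknown <- setdiff(names(cfg), known)
  if (length(unknown) > 0)
    stop(sprintf("unknown config key(s): %s", paste(unknown, collapse = ", ")),
         call. = FALSE)
  cfg
}
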