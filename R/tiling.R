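#' Midface region of interest
#'
#' A midface ROI is a union of axis-aligned rectangles in 0-based, half-open
#' pixel coordinates: a rectangle `(x0, y0, w, h)` covers columns
#' `[x0, x0 + w)` and rows `[y0, y0 + h)`.
#'
#' @param rects A data.frame (or matrix) with columns `x0`, `y0`, `w`, `h`.
#' @return An object of class `midface_roi`.
#' @export
midface_roi <- function(rects) {
  rects <- as.data.frame(rects)
  stopifnot(all(c("x0", "y0", "w", "h") %in% names(rects)))
  if (nrow(rects) == 0 || any(rects$w <= 0) || any(rects$h <= 0))
    stop("ROI must contain at least one rectangle of positive size", call. = FALSE)
  structure(list(rects = rects[, c("x0", "y0", "w", "h")]), class = "midface_roi")
}

#' @export
print.midface_roi <- function(x, ...) {
  cat(sprintf("Midface ROI: %d rectangle(s), %d px total\n",
              nrow(x$rects), sum(x$rects$w * x$rects$h)))
  invisible(x)
}

#' Canonical 62-tile midface fixture
#'
#' A stand-in midface geometry whose 20x20 tiling yields exactly 62 tiles:
#' two 100x100 px cheek blocks (5x5 tiles each) flanking a 40x120 px
#' nose/lip strip (2x6 tiles). The published study used 62 tiles over the
#' midface but gives no coordinates, so this fixture reproduces the tile
#' count, not the anatomy.
#'
#' @param offset Integer `(x, y)` pixel offset of the ROI within the frame.
#' @return A `midface_roi` tiling into exactly 62 tiles of 20x20 px.
#' @export
#' @examples
#' nrow(build_tile_grid(canonical_midface_roi())$tiles)  # 62
canonical_midface_roi <- function(offset = c(520L, 280L)) {
  ox <- offset[1]; oy <- offset[2]
  midface_roi(data.frame(
    x0 = ox + c(0L, 140L, 100L),
    y0 = oy + c(0L, 0L, 40L),
    w  = c(100L, 100L, 40L),
    h  = c(100L, 100L, 120L)))
}

roi_bbox <- function(roi) {
  r <- roi$rects
  c(x0 = min(r$x0), y0 = min(r$y0),
    x1 = max(r$x0 + r$w), y1 = max(r$y0 + r$h))
}

# Is the half-open rectangle (x0, y0, w, h) fully inside the ROI union?
# Checked pixel-wise against each ROI rectangle; tiles are small (20x20)
# so this stays cheap.
rect_in_roi <- function(x0, y0, w, h, roi) {
  r <- roi$rects
  # fast path: fully inside a single rectangle
  if (any(x0 >= r$x0 & y0 >= r$y0 & x0 + w <= r$x0 + r$w & y0 + h <= r$y0 + r$h))
    return(TRUE)
  px <- rep(x0:(x0 + w - 1L), times = h)
  py <- rep(y0:(y0 + h - 1L), each = w)
  covered <- rep(FALSE, length(px))
  for (i in seq_len(nrow(r))) {
    covered <- covered | (px >= r$x0[i] & px < r$x0[i] + r$w[i] &
                          py >= r$y0[i] & py < r$y0[i] + r$h[i])
  }
  all(covered)
}

#' Divide a midface ROI into square tiles
#'
#' Lays a `tile_size` x `tile_size` lattice anchored at the top-left corner
#' of the ROI bounding box and keeps every tile fully contained in the ROI;
#' partial edge tiles are discarded. Tiles are ordered row-major by
#' `(y0, x0)`, which fixes the tile-id assignment.
#'
#' @param roi A `midface_roi`.
#' @param tile_size Tile edge length in pixels (default 20).
#' @return An object of class `tile_grid` with a data.frame `tiles`
#'   (`tile_id`, `x0`, `y0`, `w`, `h`) and the source ROI.
#' @export
#' @examples
#' build_tile_grid(midface_roi(data.frame(x0 = 0, y0 = 0, w = 100, h = 100)))
build_tile_grid <- function(roi, tile_size = 20L) {
  stopifnot(inherits(roi, "midface_roi"))
  if (tile_size < 2) stop("tile_size must be >= 2", call. = FALSE)
  bb <- roi_bbox(roi)
  if (bb["x1"] - bb["x0"] < tile_size || bb["y1"] - bb["y0"] < tile_size)
    stop("empty grid: ROI smaller than one tile", call. = FALSE)
  xs <- seq(bb["x0"], bb["x1"] - tile_size, by = tile_size)
  ys <- seq(bb["y0"], bb["y1"] - tile_size, by = tile_size)
  cand <- expand.grid(x0 = xs, y0 = ys)            # row-major: y slow, x fast
  cand <- cand[order(cand$y0, cand$x0), ]
  keep <- vapply(seq_len(nrow(cand)), function(i)
    rect_in_roi(cand$x0[i], cand$y0[i], tile_size, tile_size, roi), logical(1))
  tiles <- cand[keep, , drop = FALSE]
  if (nrow(tiles) == 0)
    stop("empty grid: no tile fits fully inside the ROI", call. = FALSE)
  tiles$w <- tile_size
  tiles$h <- tile_size
  tiles <- data.frame(tile_id = seq_len(nrow(tiles)) - 1L,
                      x0 = tiles$x0, y0 = tiles$y0, w = tiles$w, h = tiles$h,
                      row.names = NULL)
  structure(list(tiles = tiles, tile_size = tile_size, source_roi = roi),
            class = "tile_grid")
}

#' @export
print.tile_grid <- function(x, ...) {
  cat(sprintf("Tile grid: %d tiles of %dx%d px\n",
              nrow(x$tiles), x$tile_size, x$tile_size))
  invisible(x)
}

#' Per-tile signal matrix
#'
#' Container for the frames x tiles matrix of mean green-channel values.
#'
#' @param values Numeric matrix, frames in rows, tiles in columns, ADC units.
#' @param fps Sampling rate in Hz.
#' @param tile_ids Integer tile ids aligned to the columns (default 0-based
#'   sequence).
#' @return An object of class `tile_signal_matrix`.
#' @export
tile_signal_matrix <- function(values, fps, tile_ids = seq_len(ncol(values)) - 1L) {
  values <- as.matrix(values)
  if (!all(is.finite(values)))
    stop("tile signals contain non-finite values", call. = FALSE)
  stopifnot(length(tile_ids) == ncol(values), fps > 0)
  structure(list(values = values, fps = fps, tile_ids = as.integer(tile_ids),
                 t0 = 0),
            class = "tile_signal_matrix")
}

#' @export
print.tile_signal_matrix <- function(x, ...) {
  cat(sprintf("Tile signals: %d frames x %d tiles @ %g Hz (%.1f s)\n",
              nrow(x$values), ncol(x$values), x$fps, nrow(x$values) / x$fps))
  invisible(x)
}

#' @export
dim.tile_signal_matrix <- function(x) dim(x$values)

#' Extract per-tile mean green signals from a frame stack
#'
#' For each frame, takes the arithmetic mean of the green channel over each
#' tile's pixels, producing the tile-signal matrix that all downstream
#' scoring and aggregation consumes.
#'
#' @param frames A `frame_stack` (see [render_frames()] / [read_frames()])
#'   or a numeric array with dimensions height x width x channel x frame.
#' @param grid A `tile_grid`.
#' @return A `tile_signal_matrix` in ADC units.
#' @export
extract_tile_signals <- function(frames, grid) {
  stopifnot(inherits(grid, "tile_grid"))
  if (inherits(frames, "frame_stack")) {
    arr <- frames$pixels
    fps <- frames$fps
  } else {
    arr <- frames
    fps <- attr(frames, "fps")
    if (is.null(fps)) stop("frame array lacks an fps attribute", call. = FALSE)
  }
  d <- dim(arr)
  if (length(d) != 4)
    stop("frames must be a height x width x channel x frame array", call. = FALSE)
  if (d[4] == 0) stop("empty input: no frames", call. = FALSE)
  tiles <- grid$tiles
  if (any(tiles$x0 < 0 | tiles$y0 < 0 |
          tiles$x0 + tiles$w > d[2] | tiles$y0 + tiles$h > d[1]))
    stop("tile out of frame bounds", call. = FALSE)
  nt <- nrow(tiles)
  vals <- matrix(NA_real_, nrow = d[4], ncol = nt)
  for (k in seq_len(nt)) {
    rows <- (tiles$y0[k] + 1L):(tiles$y0[k] + tiles$h[k])
    cols <- (tiles$x0[k] + 1L):(tiles$x0[k] + tiles$w[k])
    block <- arr[rows, cols, 2L, , drop = FALSE]        # green channel
    vals[, k] <- colMeans(matrix(block, ncol = d[4]))
  }
  tile_signal_matrix(vals, fps = fps, tile_ids = tiles$tile_id)
}
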