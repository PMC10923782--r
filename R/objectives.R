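## Construction and assignment of per-cell control objectives: constants,
## sinewaves with positional phase delays, and movie-pixel trajectories.

#' Constant setpoint objective
#'
#' @param level target fluorescence (a.u.)
#' @param T_points number of 5-min timepoints
#' @param cell_id assigned cell
#' @param start_time control onset (h)
#' @return An [ObjectiveTrack-class].
#' @export
constantObjective <- function(level, T_points, cell_id = "cell",
                              start_time = 3) {
  new("ObjectiveTrack", values = rep(level, T_points),
      cell_id = as.character(cell_id), start_time = start_time)
}

#' Sinewave objective
#'
#' `values[t] = offset + amplitude * sin(2*pi*t*dt/period + phase)` on the
#' 5-min grid (t starting at 0). Per-cell phase delays turn a shared
#' sinewave into spatial patterns such as expanding concentric rings.
#'
#' @param amplitude amplitude (a.u.); `offset >= amplitude` keeps the
#'   track non-negative
#' @param period period in hours
#' @param phase phase (radians)
#' @param offset mean level (a.u.)
#' @param T_points number of timepoints
#' @param dt_min sampling interval (min)
#' @param cell_id assigned cell
#' @param start_time control onset (h)
#' @return An [ObjectiveTrack-class].
#' @export
#' @examples
#' sinewaveObjective(400, 6, 0, 1200, 192)
sinewaveObjective <- function(amplitude, period, phase = 0, offset = 1200,
                              T_points = 192, dt_min = 5, cell_id = "cell",
                              start_time = 3) {
  if (period <= 0) stop("period must be > 0")
  if (offset < amplitude)
    stop("offset must be >= amplitude to keep the objective non-negative")
  t_h <- (seq_len(T_points) - 1) * dt_min / 60
  v <- offset + amplitude * sin(2 * pi * t_h / period + phase)
  new("ObjectiveTrack", values = v, cell_id = as.character(cell_id),
      start_time = start_time)
}

#' Movie-pixel objective set
#'
#' Turns a stack of grayscale frames into per-cell objective tracks: each
#' pixel's intensity timeseries, linearly mapped from [0, 1] to
#' `[lo_au, hi_au]`, becomes the target trajectory of one cell. Pixels are
#' randomly shuffled before assignment (the permutation is returned so the
#' movie can be de-shuffled after the experiment) and frames are held to
#' the 5-min grid (nearest earlier frame).
#'
#' @param frames W x H x F numeric array with intensities in [0, 1] (PNG
#'   frames read with `png::readPNG` have this form)
#' @param n_cells number of tracks to assign (at most W x H)
#' @param lo_au,hi_au intensity mapping bounds (a.u.); defaults bracket
#'   the 800-1800 a.u. working band
#' @param frame_interval_min movie frame interval (min)
#' @param T_points length of the tracks on the 5-min grid; defaults to the
#'   movie duration
#' @param seed shuffle seed
#' @param offset skip this many shuffled pixels (to split one movie across
#'   experiment batches)
#' @param start_time control onset (h)
#' @return list with `tracks` (list of [ObjectiveTrack-class]),
#'   `permutation` (pixel order), and `pixel_index` (the pixel backing
#'   each track).
#' @export
movieObjectives <- function(frames, n_cells, lo_au = 400, hi_au = 2000,
                            frame_interval_min = 5, T_points = NULL,
                            seed = 1L, offset = 0L, start_time = 3) {
  d <- dim(frames)
  if (is.null(d) || length(d) != 3L || d[3] < 1L)
    stop("frames must be a W x H x F array with at least one frame")
  n_pix <- d[1] * d[2]
  if (offset + n_cells > n_pix)
    stop("n_cells + offset exceeds the ", n_pix, " available pixels")
  set.seed(as.integer(seed))
  perm <- sample(n_pix)
  sel <- perm[(offset + 1):(offset + n_cells)]
  if (is.null(T_points))
    T_points <- ceiling(d[3] * frame_interval_min / 5)
  t_min <- (seq_len(T_points) - 1) * 5
  frame_idx <- pmin(d[3], floor(t_min / frame_interval_min) + 1)
  flat <- matrix(frames, n_pix, d[3])
  tracks <- lapply(seq_along(sel), function(k) {
    inten <- flat[sel[k], frame_idx]
    new("ObjectiveTrack", values = lo_au + inten * (hi_au - lo_au),
        cell_id = sprintf("px%05d", sel[k]), start_time = start_time)
  })
  list(tracks = tracks, permutation = perm, pixel_index = sel)
}

#' Read a stack of grayscale PNG frames
#'
#' Loads image files into the W x H x F array consumed by
#' [movieObjectives()]; RGB images are averaged to grayscale.
#'
#' @param files character vector of PNG paths, in frame order
#' @return numeric W x H x F array with intensities in [0, 1].
#' @export
readFrameStack <- function(files) {
  if (!requireNamespace("png", quietly = TRUE))
    stop("reading PNG frames requires the 'png' package")
  frames <- lapply(files, function(f) {
    img <- png::readPNG(f)
    if (length(dim(img)) == 3L) img <- apply(img[, , 1:3], c(1, 2), mean)
    t(img)   # image rows are y; store as W x H
  })
  array(unlist(frames), c(dim(frames[[1]]), length(frames)))
}

#' Time-derivative of an objective track
#'
#' Forward finite differences on the 5-min grid, in a.u./h; the last entry
#' is `NA` to keep the series aligned.
#'
#' @param track an [ObjectiveTrack-class] or numeric vector
#' @param dt_min sampling interval (min)
#' @return numeric vector of derivatives (a.u./h).
#' @export
objectiveDerivative <- function(track, dt_min = 5) {
  v <- if (is(track, "ObjectiveTrack")) track@values else as.numeric(track)
  if (length(v) < 2) stop("track must have length >= 2")
  c(diff(v), NA_real_) / (dt_min / 60)
}
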